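# SUN-SEG-style clip dataset handling: directory scanning, the
# first-clip-per-polyp filter, temporal windowing, loading/resizing, and
# window-consistent augmentation.
#
# Expected layout:
#   root/
#     attributes.csv            (clip_id, attributes[, polyp_case_id])
#     <clip_id>/Frame/*.png|jpg (RGB frames, sorted by filename)
#     <clip_id>/GT/*.png        (binary masks, 1:1 with frames)

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Scan a clip dataset directory
#'
#' @param root dataset directory (see layout above). The attributes CSV
#'   stores labels as a semicolon-separated column; `polyp_case_id`
#'   defaults to the part of the clip id before the last underscore.
#' @return list of `clip_record`s (clip_id, polyp_case_id, frame_paths,
#'   mask_paths, attributes), sorted by clip id. Clips with no frames are
#'   skipped with a warning; a frame without a mask is an error.
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  att_path <- file.path(root, "attributes.csv")
  att <- NULL
  if (file.exists(att_path))
    att <- utils::read.csv(att_path, stringsAsFactors = FALSE)
  clip_dirs <- sort(list.dirs(root, recursive = FALSE))
  records <- list()
  for (cd in clip_dirs) {
    clip_id <- basename(cd)
    fdir <- file.path(cd, "Frame"); gdir <- file.path(cd, "GT")
    if (!dir.exists(fdir)) next
    frames <- sort(list.files(fdir, pattern = "\\.(png|jpg|jpeg)$",
                              ignore.case = TRUE, full.names = TRUE))
    if (length(frames) == 0) {
      warning("clip ", clip_id, " has no frames; skipped")
      next
    }
    masks <- file.path(gdir, sub("\\.(jpg|jpeg)$", ".png",
                                 basename(frames), ignore.case = TRUE))
    missing <- !file.exists(masks)
    if (any(missing))
      stop("missing mask for frame ", basename(frames[which(missing)[1]]),
           " of clip ", clip_id)
    attrs <- character(0)
    case_id <- sub("_[^_]*$", "", clip_id)
    if (!is.null(att)) {
      row <- att[att$clip_id == clip_id, , drop = FALSE]
      if (nrow(row)) {
        av <- as.character(row$attributes[1])
        if (!is.na(av) && nzchar(av))
          attrs <- strsplit(av, ";", fixed = TRUE)[[1]]
        if ("polyp_case_id" %in% names(row)) case_id <- row$polyp_case_id[1]
      }
    }
    bad <- setdiff(attrs, ATTRIBUTE_IDS)
    if (length(bad))
      stop("clip ", clip_id, " carries unknown attribute(s): ",
           paste(bad, collapse = ", "))
    records[[length(records) + 1L]] <-
      structure(list(clip_id = clip_id, polyp_case_id = case_id,
                     frame_paths = frames, mask_paths = masks,
                     attributes = attrs),
                class = "clip_record")
  }
  records[order(vapply(records, `[[`, "", "clip_id"))]
}

#' Keep only the first clip of each polyp case
#'
#' The lexicographically first clip id wins, mirroring the training-set
#' reduction rule used with SUN-SEG.
#'
#' @param records list of clip records from [scan_dataset()].
#' @return filtered list, one record per polyp case.
#' @export
first_clip_per_polyp <- function(records) {
  ids <- vapply(records, `[[`, "", "clip_id")
  cases <- vapply(records, `[[`, "", "polyp_case_id")
  ord <- order(ids)
  keep <- ord[!duplicated(cases[ord])]
  records[sort(keep)]
}

#' Split a clip into temporal windows of F consecutive frames
#'
#' Non-overlapping windows by default (stride = F); when the clip length
#' is not divisible by the stride, a final window anchored at the clip
#' end is added (overlapping the previous one) so every frame is covered.
#' Clips shorter than F yield no windows, with a warning.
#'
#' @param record a clip record.
#' @param F window length in frames.
#' @param stride step between window starts (default `F`).
#' @return list of windows: `list(clip_id, start, length)` with 0-based
#'   `start`.
#' @export
make_windows <- function(record, F = 5L, stride = F) {
  stopifnot(F >= 1L, stride >= 1L)
  L <- length(record$frame_paths)
  if (L < F) {
    warning("clip ", record$clip_id, " has ", L, " < F = ", F,
            " frames; skipped")
    return(list())
  }
  starts <- seq.int(0L, L - F, by = stride)
  if (max(starts) + F < L) starts <- c(starts, L - F)
  lapply(starts, function(s)
    list(clip_id = record$clip_id, start = as.integer(s),
         length = as.integer(F)))
}

read_rgb <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else jpeg::readJPEG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

resize_bilinear <- function(img, H, W) {
  out <- array(0, c(H, W, dim(img)[3]))
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- EBImage::imageData(
      EBImage::resize(EBImage::Image(img[, , ch]), w = H, h = W,
                      filter = "bilinear"))
  out
}

resize_nearest <- function(m, H, W) {
  EBImage::imageData(EBImage::resize(EBImage::Image(m * 1), w = H, h = W,
                                     filter = "none"))
}

#' Load one window of frames and masks
#'
#' Frames are resized bilinearly to `size`, masks with nearest-neighbour
#' and binarized at 0.5. Intensity normalization is `[0, 1]` scaling by
#' default, or fixed channel mean/sd standardization (the pretrained
#' backbone convention) when `normalize = "imagenet"`.
#'
#' @param record a clip record.
#' @param window a window from [make_windows()].
#' @param size target c(H, W).
#' @param normalize `"unit"` or `"imagenet"`.
#' @return list with `frames` (H x W x 3 x F) and `masks` (H x W x 1 x F,
#'   values 0/1).
#' @export
load_window <- function(record, window, size = c(256L, 256L),
                        normalize = c("unit", "imagenet")) {
  normalize <- match.arg(normalize)
  H <- size[1]; W <- size[2]
  F <- window$length
  idx <- window$start + seq_len(F)
  frames <- array(0, c(H, W, 3, F))
  masks <- array(0, c(H, W, 1, F))
  for (k in seq_len(F)) {
    img <- tryCatch(read_rgb(record$frame_paths[idx[k]]),
                    error = function(e)
                      stop("unreadable frame ", record$frame_paths[idx[k]],
                           ": ", conditionMessage(e)))
    if (!identical(dim(img)[1:2], as.integer(c(H, W))))
      img <- resize_bilinear(img, H, W)
    if (normalize == "imagenet") {
      for (ch in 1:3)
        img[, , ch] <- (img[, , ch] - IMAGENET_MEAN[ch]) / IMAGENET_SD[ch]
    }
    frames[, , , k] <- img
    m <- png::readPNG(record$mask_paths[idx[k]])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (!identical(dim(m), as.integer(c(H, W))))
      m <- resize_nearest(m, H, W)
    masks[, , 1, k] <- (m > 0.5) * 1
  }
  list(frames = frames, masks = masks)
}

draw_augment_params <- function(config = list()) {
  rot_range <- config$rot_range %||% 20
  crop_range <- config$crop_range %||% c(0.8, 1.0)
  list(angle = stats::runif(1, -rot_range, rot_range),
       hflip = stats::runif(1) < 0.5,
       vflip = stats::runif(1) < 0.5,
       crop_scale = stats::runif(1, crop_range[1], crop_range[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_geom <- function(img, params, nearest = FALSE) {
  H <- dim(img)[1]; W <- dim(img)[2]
  filt <- if (nearest) "none" else "bilinear"
  e <- EBImage::Image(img, colormode = if (length(dim(img)) == 3L)
    "Color" else "Grayscale")
  e <- EBImage::rotate(e, params$angle, filter = filt,
                       output.dim = c(H, W), bg.col = 0)
  out <- EBImage::imageData(e)
  if (length(dim(out)) == 2L) dim(out) <- c(H, W, 1L)
  if (params$hflip) out <- out[, W:1, , drop = FALSE]
  if (params$vflip) out <- out[H:1, , , drop = FALSE]
  s <- params$crop_scale
  if (s < 1) {
    ch <- max(16L, 2L * floor(s * H / 2)); cw <- max(16L, 2L * floor(s * W / 2))
    r0 <- (H - ch) %/% 2L; c0 <- (W - cw) %/% 2L
    cropped <- out[r0 + seq_len(ch), c0 + seq_len(cw), , drop = FALSE]
    res <- array(0, c(H, W, dim(out)[3]))
    for (k in seq_len(dim(out)[3]))
      res[, , k] <- EBImage::imageData(
        EBImage::resize(EBImage::Image(cropped[, , k]), w = H, h = W,
                        filter = filt))
    out <- res
  }
  out
}

#' Augment a window with one shared random draw
#'
#' A single draw of (rotation angle, horizontal flip, vertical flip,
#' centre-crop scale) is applied identically to every frame and mask of
#' the window; masks use nearest-neighbour resampling and are
#' re-binarized.
#'
#' @param frames array H x W x 3 x F.
#' @param masks array H x W x 1 x F (0/1).
#' @param seed optional seed; when given the draw is made under it
#'   without disturbing the caller's RNG stream.
#' @param config optional list with `rot_range` (degrees, default 20) and
#'   `crop_range` (default c(0.8, 1)).
#' @param params optionally, a previously drawn parameter list to reuse.
#' @return list with augmented `frames`, `masks` and the `params` used.
#' @export
augment_window <- function(frames, masks, seed = NULL, config = list(),
                           params = NULL) {
  if (is.null(params)) {
    params <- if (!is.null(seed))
      with_seed(seed, draw_augment_params(config))
    else draw_augment_params(config)
  }
  F <- dim(frames)[4]
  out_f <- array(0, dim(frames))
  out_m <- array(0, dim(masks))
  for (k in seq_len(F)) {
    fr <- frames[, , , k]
    dim(fr) <- dim(frames)[1:3]
    out_f[, , , k] <- apply_geom(fr, params)
    mk <- masks[, , 1, k]
    dim(mk) <- c(dim(masks)[1:2], 1L)
    mm <- apply_geom(mk, params, nearest = TRUE)
    out_m[, , 1, k] <- (mm[, , 1] > 0.5) * 1
  }
  list(frames = out_f, masks = out_m, params = params)
}

#' Seed-deterministic k-fold split at clip level
#'
#' @param records list of clip records.
#' @param k number of folds.
#' @param seed RNG seed; the same seed yields the same partition.
#' @return list of k folds, each `list(train, val)` of clip ids; the val
#'   sets partition the clip ids.
#' @export
make_folds <- function(records, k = 5L, seed = 1L) {
  ids <- vapply(records, `[[`, "", "clip_id")
  if (k > length(ids)) stop("k = ", k, " exceeds number of clips (",
                            length(ids), ")")
  perm <- with_seed(seed, sample(ids))
  assignment <- rep_len(seq_len(k), length(ids))
  lapply(seq_len(k), function(f) {
    val <- sort(perm[assignment == f])
    list(train = sort(setdiff(ids, val)), val = val)
  })
}

#' Stack loaded windows into a clip batch
#'
#' @param windows list of `load_window()` results (equal sizes).
#' @return list with `clips` (B x F x 3 x H x W) and `masks`
#'   (B x F x 1 x H x W).
#' @export
stack_windows <- function(windows) {
  B <- length(windows)
  d <- dim(windows[[1]]$frames)  # H W 3 F
  clips <- array(0, c(B, d[4], 3, d[1], d[2]))
  masks <- array(0, c(B, d[4], 1, d[1], d[2]))
  for (i in seq_len(B)) {
    clips[i, , , , ] <- aperm(windows[[i]]$frames, c(4, 3, 1, 2))
    masks[i, , , , ] <- aperm(windows[[i]]$masks, c(4, 3, 1, 2))
  }
  list(clips = clips, masks = masks)
}
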