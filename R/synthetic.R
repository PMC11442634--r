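# Synthetic colonoscopy-like clips: a deformable bright elliptical blob
# moving over a smooth textured background, with ground-truth masks and
# rule-based visual-attribute labels. The clips exercise the data
# pipeline's geometry and the numeric attribute rules; they make no
# attempt at photorealism.

FM_THRESHOLD_PX <- 20      # mean per-frame centroid motion
SO_THRESHOLD <- 0.05       # mean object area / image area
LO_THRESHOLD <- 0.15       # mean bbox area / image area
SV_THRESHOLD <- 0.5        # min pairwise bbox area ratio

# Evaluate an expression under a given seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic clip
#'
#' @param n_frames number of frames.
#' @param image_size c(H, W) in pixels.
#' @param trajectory n_frames x 2 matrix of blob centers (row, col); if
#'   `NULL`, built from `center`, `velocity` and reflection at the canvas
#'   margins.
#' @param center starting center c(row, col); default canvas center.
#' @param velocity per-frame displacement c(drow, dcol) in pixels.
#' @param axes ellipse semi-axes, either c(a, b) or an n_frames x 2
#'   matrix for per-frame scale change.
#' @param angle ellipse orientation in radians (scalar or per frame).
#' @param brightness peak intensity added at the blob center.
#' @param edge_softness width (px) of the blob's soft intensity edge; the
#'   ground-truth mask is always the hard ellipse interior.
#' @param occlusion if TRUE, a dark vertical band crosses the blob in the
#'   middle frames, erasing image and mask there.
#' @param ghost_shift horizontal offset (px) of a colour fringe at the
#'   blob boundary (0 = off).
#' @param seed RNG seed for the background texture.
#' @return a `synth_clip_spec` list.
#' @export
synth_clip_spec <- function(n_frames = 10L, image_size = c(256L, 256L),
                            trajectory = NULL, center = NULL,
                            velocity = c(0, 0), axes = NULL, angle = 0,
                            brightness = 0.35, edge_softness = 2,
                            occlusion = FALSE, ghost_shift = 0,
                            seed = 1L) {
  H <- image_size[1]; W <- image_size[2]
  if (is.null(axes)) axes <- c(0.12, 0.09) * min(H, W)
  if (is.matrix(axes)) {
    stopifnot(nrow(axes) == n_frames)
  } else {
    axes <- matrix(rep(axes, each = n_frames), n_frames, 2)
  }
  if (any(axes <= 0)) stop("ellipse axes must be positive")
  if (is.null(trajectory)) {
    if (is.null(center)) center <- c(H / 2, W / 2)
    trajectory <- matrix(0, n_frames, 2)
    pos <- center; vel <- velocity
    margin <- c(max(axes[, 1]), max(axes[, 2])) * 0.5
    for (f in seq_len(n_frames)) {
      trajectory[f, ] <- pos
      pos <- pos + vel
      for (k in 1:2) {  # reflect at margins so fast blobs stay on canvas
        lo <- margin[k]; hi <- c(H, W)[k] - margin[k]
        if (pos[k] < lo) { pos[k] <- 2 * lo - pos[k]; vel[k] <- -vel[k] }
        if (pos[k] > hi) { pos[k] <- 2 * hi - pos[k]; vel[k] <- -vel[k] }
      }
    }
  }
  if (nrow(trajectory) != n_frames)
    stop("trajectory must have one row per frame")
  angle <- rep(angle, length.out = n_frames)
  structure(list(n_frames = as.integer(n_frames),
                 image_size = as.integer(image_size),
                 trajectory = trajectory, axes = axes, angle = angle,
                 brightness = brightness, edge_softness = edge_softness,
                 occlusion = isTRUE(occlusion), ghost_shift = ghost_shift,
                 seed = as.integer(seed)),
            class = "synth_clip_spec")
}

smooth_background <- function(H, W) {
  coarse_h <- max(4L, H %/% 16L); coarse_w <- max(4L, W %/% 16L)
  base <- c(0.45, 0.30, 0.26)  # mucosa-like reddish tone
  bg <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    coarse <- matrix(stats::runif(coarse_h * coarse_w, -0.08, 0.08),
                     coarse_h, coarse_w)
    sm <- EBImage::resize(EBImage::Image(coarse), w = H, h = W)
    bg[, , ch] <- base[ch] + EBImage::imageData(sm) +
      stats::rnorm(H * W, 0, 0.01)
  }
  bg
}

ellipse_quadform <- function(H, W, cy, cx, a, b, theta) {
  y <- matrix(seq_len(H), H, W) - cy
  x <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * y + sin(theta) * x
  v <- -sin(theta) * y + cos(theta) * x
  (u / a)^2 + (v / b)^2
}

#' Render a synthetic clip
#'
#' Deterministic under the spec's seed: the same spec yields bit-identical
#' frames and masks. The mask is the hard ellipse interior, clipped to
#' the canvas; the image shows a soft-edged brighter blob over a smooth
#' textured background.
#'
#' @param spec a [synth_clip_spec()].
#' @return list with `frames` (array H x W x 3 x n, values in `[0, 1]`),
#'   `masks` (logical array H x W x n) and the spec.
#' @export
render_clip <- function(spec) {
  stopifnot(inherits(spec, "synth_clip_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  n <- spec$n_frames
  with_seed(spec$seed, {
    bg <- smooth_background(H, W)
    frames <- array(0, c(H, W, 3, n))
    masks <- array(FALSE, c(H, W, n))
    chan_gain <- c(1, 0.7, 0.6)
    occ_frames <- if (spec$occlusion)
      seq.int(max(1L, floor(n / 3)), ceiling(2 * n / 3)) else integer(0)
    for (f in seq_len(n)) {
      cy <- spec$trajectory[f, 1]; cx <- spec$trajectory[f, 2]
      a <- spec$axes[f, 1]; b <- spec$axes[f, 2]
      q <- ellipse_quadform(H, W, cy, cx, a, b, spec$angle[f])
      mask <- q <= 1
      # signed pseudo-distance to the ellipse edge, in pixels
      sdist <- (1 - sqrt(q)) * min(a, b)
      profile <- stats::plogis(sdist / spec$edge_softness)
      img <- bg
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] + spec$brightness * chan_gain[ch] * profile
      if (spec$ghost_shift != 0) {
        shift <- round(spec$ghost_shift)
        shifted <- mask
        if (shift > 0) {
          shifted <- cbind(matrix(FALSE, H, shift),
                           mask[, seq_len(W - shift), drop = FALSE])
        } else if (shift < 0) {
          shifted <- cbind(mask[, (-shift + 1):W, drop = FALSE],
                           matrix(FALSE, H, -shift))
        }
        fringe <- xor(mask, shifted)
        img[, , 1][fringe] <- img[, , 1][fringe] + 0.25
        img[, , 2][fringe] <- img[, , 2][fringe] - 0.10
      }
      if (f %in% occ_frames) {
        half <- max(2L, W %/% 16L)
        cols <- max(1L, round(cx) - half):min(W, round(cx) + half)
        img[, cols, ] <- 0.08
        mask[, cols] <- FALSE
      }
      frames[, , , f] <- pmin(pmax(img, 0), 1)
      masks[, , f] <- mask
    }
    list(frames = frames, masks = masks, spec = spec)
  })
}

mask_bbox_area <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
}

mask_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Label a mask sequence with the numeric visual attributes
#'
#' Implements the threshold rules: FM (fast motion) if the mean Euclidean
#' centroid displacement between consecutive frames exceeds 20 px; SO
#' (small object) if the mean object-area/image-area ratio is below 0.05;
#' LO (large object) if the mean bounding-box/image-area ratio exceeds
#' 0.15; SV (scale variation) if the minimum pairwise bounding-box area
#' ratio (smaller over larger) is below 0.5. Frames with empty masks are
#' excluded from the means.
#'
#' @param masks logical array H x W x n or list of logical matrices.
#' @return character vector, subset of c("FM", "SO", "LO", "SV").
#' @export
label_attributes <- function(masks) {
  if (is.list(masks)) masks <- simplify2array(masks)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  n <- dim(masks)[3]
  H <- dim(masks)[1]; W <- dim(masks)[2]
  nonempty <- vapply(seq_len(n), function(f) any(masks[, , f]), logical(1))
  if (!any(nonempty)) stop("all masks in the sequence are empty")
  labels <- character(0)
  areas <- vapply(which(nonempty), function(f) sum(masks[, , f]), numeric(1))
  bboxes <- vapply(which(nonempty), function(f)
    mask_bbox_area(masks[, , f]), numeric(1))
  cents <- t(vapply(which(nonempty), function(f)
    mask_centroid(masks[, , f]), numeric(2)))
  if (sum(nonempty) >= 2) {
    # consecutive pairs among frames that are both non-empty
    ne <- which(nonempty)
    steps <- which(diff(ne) == 1)
    if (length(steps)) {
      disp <- sqrt(rowSums((cents[steps + 1, , drop = FALSE] -
                              cents[steps, , drop = FALSE])^2))
      if (mean(disp) > FM_THRESHOLD_PX) labels <- c(labels, "FM")
    }
  }
  if (mean(areas / (H * W)) < SO_THRESHOLD) labels <- c(labels, "SO")
  if (mean(bboxes / (H * W)) > LO_THRESHOLD) labels <- c(labels, "LO")
  if (length(bboxes) >= 2) {
    rat <- outer(bboxes, bboxes, function(p, q) pmin(p, q) / pmax(p, q))
    if (min(rat[upper.tri(rat)]) < SV_THRESHOLD) labels <- c(labels, "SV")
  }
  labels
}

# Archetype specs exercising each rule-based attribute plus artifacts.
benchmark_archetypes <- function(image_size, n_frames, seed) {
  H <- image_size[1]; W <- image_size[2]
  S <- min(H, W)
  small_r <- sqrt(0.01 * H * W / pi)  # area ratio ~0.01 -> SO
  list(
    plain = synth_clip_spec(n_frames, image_size,
                            velocity = c(0.4, 0.6), seed = seed),
    so_small = synth_clip_spec(n_frames, image_size,
                               axes = c(small_r, small_r),
                               velocity = c(0.3, 0.4), seed = seed + 1L),
    lo_large = synth_clip_spec(n_frames, image_size,
                               axes = c(0.23 * H, 0.21 * W),
                               velocity = c(0.2, 0.3), seed = seed + 2L),
    fm_fast = synth_clip_spec(n_frames, image_size,
                              velocity = c(18, 18),
                              axes = c(0.1, 0.08) * S, seed = seed + 3L),
    sv_grow = synth_clip_spec(n_frames, image_size,
                              axes = cbind(seq(0.07 * S, 0.14 * S,
                                               length.out = n_frames),
                                           seq(0.06 * S, 0.12 * S,
                                               length.out = n_frames)),
                              velocity = c(0.2, 0.2), seed = seed + 4L),
    occ = synth_clip_spec(n_frames, image_size, velocity = c(0.3, 0.4),
                          axes = c(0.17 * H, 0.16 * W),
                          occlusion = TRUE, seed = seed + 5L),
    gh = synth_clip_spec(n_frames, image_size, velocity = c(0.3, 0.4),
                         ghost_shift = 3, seed = seed + 6L)
  )
}

#' Write a benchmark dataset tree of synthetic clips
#'
#' Generates `n_clips` polyp cases cycling through archetypes (small,
#' large, fast, growing, occluded, ghosted, plain blobs) and writes a
#' dataset tree in the layout [scan_dataset()] reads: one directory per
#' clip with `Frame/` and `GT/` PNGs plus an `attributes.csv` whose
#' labels come from [label_attributes()] (and the construction flags OCC
#' and GH for the artifact variants).
#'
#' @param dir output directory.
#' @param n_clips number of polyp cases.
#' @param seed RNG seed.
#' @param image_size c(H, W) of the generated frames.
#' @param n_frames frames per clip.
#' @param clips_per_polyp clips per polyp case (recycled); additional
#'   clips of the same case re-render with a different texture seed.
#' @return invisibly, the data.frame written to `attributes.csv`.
#' @export
make_benchmark_suite <- function(dir, n_clips = 6L, seed = 1L,
                                 image_size = c(256L, 256L),
                                 n_frames = 10L, clips_per_polyp = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arch <- benchmark_archetypes(image_size, n_frames, seed)
  kinds <- names(arch)
  cpp <- rep_len(clips_per_polyp, n_clips)
  rows <- list()
  for (i in seq_len(n_clips)) {
    kind <- kinds[(i - 1L) %% length(kinds) + 1L]
    case_id <- sprintf("case%03d", i)
    for (j in seq_len(cpp[i])) {
      spec <- arch[[kind]]
      spec$seed <- spec$seed + 100L * i + j - 1L
      clip <- render_clip(spec)
      clip_id <- sprintf("%s_%d", case_id, j)
      write_clip(clip, file.path(dir, clip_id))
      labs <- tryCatch(label_attributes(clip$masks),
                       error = function(e) character(0))
      if (spec$occlusion) labs <- union(labs, "OCC")
      if (spec$ghost_shift != 0) labs <- union(labs, "GH")
      rows[[length(rows) + 1L]] <-
        data.frame(clip_id = clip_id, polyp_case_id = case_id,
                   attributes = paste(labs, collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(dir, "attributes.csv"), row.names = FALSE)
  invisible(tab)
}

#' Write one rendered clip as a Frame/ + GT/ PNG directory
#'
#' @param clip result of [render_clip()].
#' @param clip_dir output directory for this clip.
#' @return the directory, invisibly.
#' @export
write_clip <- function(clip, clip_dir) {
  fdir <- file.path(clip_dir, "Frame")
  gdir <- file.path(clip_dir, "GT")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(clip$frames)[4]
  for (f in seq_len(n)) {
    png::writePNG(clip$frames[, , , f],
                  file.path(fdir, sprintf("frame_%04d.png", f)))
    png::writePNG(clip$masks[, , f] * 1,
                  file.path(gdir, sprintf("frame_%04d.png", f)))
  }
  invisible(clip_dir)
}
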