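# Seeded training loop (Adam, Dice+BCE, many-to-many supervision),
# evaluation runner and parameter-count verifier.

#' Training configuration
#'
#' Defaults mirror the published setup: Adam at learning rate 1e-4,
#' 5 consecutive frames, batch size 8 (so the encoder/decoder see a
#' flattened batch of 40), 5-fold cross-validation, 100 epochs, frames
#' standardized to 256 x 256. Smoke-scale runs override `epochs`,
#' `image_size` and `max_steps`.
#'
#' @param lr Adam learning rate.
#' @param epochs training epochs per fold.
#' @param batch windows per optimization step.
#' @param frames window length F.
#' @param folds number of cross-validation folds; `folds = 1` is a
#'   degenerate smoke mode where the single fold trains and validates on
#'   all clips.
#' @param seed master seed; all RNG (shuffling, augmentation draws,
#'   weight init) derives from it, so reruns are bit-identical.
#' @param image_size c(H, W) the loader resizes to (divisible by 16).
#' @param stride window stride (default `frames`).
#' @param augment apply window-consistent augmentation to training data.
#' @param normalize `"unit"` or `"imagenet"` intensity normalization.
#' @param max_steps optional cap on optimization steps per fold.
#' @param val_every validate every this many epochs (always at the end).
#' @param target_val_dice optional early-stop threshold: stop the fold
#'   once its validation Dice reaches this value (checked at validation
#'   points). In the `folds = 1` smoke mode validation Dice is the
#'   training-clip Dice.
#' @param out_dir directory for checkpoints and logs (`NULL` = no files).
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, epochs = 100L, batch = 8L, frames = 5L,
                         folds = 5L, seed = 1L,
                         image_size = c(256L, 256L), stride = NULL,
                         augment = TRUE, normalize = "unit",
                         max_steps = NULL, val_every = 1L,
                         target_val_dice = NULL, out_dir = NULL,
                         verbose = FALSE) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch = as.integer(batch), frames = as.integer(frames),
                 folds = as.integer(folds), seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 stride = as.integer(stride %||% frames),
                 augment = isTRUE(augment), normalize = normalize,
                 max_steps = max_steps, val_every = as.integer(val_every),
                 target_val_dice = target_val_dice, out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) 0)
  st$v <- lapply(params, function(p) 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    p$value <- p$value - opt$lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  invisible(NULL)
}

# ---- data plumbing ----------------------------------------------------------

# Load (and cache) every window of a record at the configured size.
window_cache <- function() new.env(parent = emptyenv())

load_window_cached <- function(cache, record, window, cfg) {
  key <- paste0(record$clip_id, "@", window$start)
  if (is.null(cache[[key]]))
    cache[[key]] <- load_window(record, window, cfg$image_size,
                                cfg$normalize)
  cache[[key]]
}

records_by_id <- function(records) {
  stats::setNames(records, vapply(records, `[[`, "", "clip_id"))
}

# ---- training ---------------------------------------------------------------

#' Train the network with k-fold cross-validation
#'
#' Per fold: the model is built from the fold-specific seed and optimized
#' with Adam on the combined Dice + BCE loss over all F output frames
#' (many-to-many supervision). After every epoch the fold's held-out
#' clips are evaluated and the checkpoint with the best validation Dice
#' is kept. The whole run is deterministic under `cfg$seed`.
#'
#' @param cfg a [train_config()].
#' @param records clip records from [scan_dataset()] (already filtered as
#'   desired, e.g. by [first_clip_per_polyp()]).
#' @return list of per-fold results: `checkpoint` (path or in-memory
#'   model), `history` (per-epoch data.frame), `best_val_dice`,
#'   `final_loss`, `train_dice`.
#' @export
train_model <- function(cfg, records) {
  if (length(records) == 0) stop("no clips to train on")
  if (cfg$folds > 1 && cfg$folds > length(records))
    stop("fold count exceeds number of clips")
  recmap <- records_by_id(records)
  folds <- if (cfg$folds == 1) {
    ids <- names(recmap)
    list(list(train = ids, val = ids))
  } else make_folds(records, cfg$folds, cfg$seed)
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  lapply(seq_along(folds), function(k)
    train_one_fold(cfg, recmap, folds[[k]], k))
}

train_one_fold <- function(cfg, recmap, fold, k) {
  set.seed(cfg$seed + 1000L * k)
  model <- build_polypnextlstm(model_config())
  params <- collect_parameters(model)
  opt <- adam_new(params, cfg$lr)
  cache <- window_cache()
  train_recs <- recmap[fold$train]
  windows <- list()
  for (r in train_recs)
    for (w in make_windows(r, cfg$frames, cfg$stride))
      windows[[length(windows) + 1L]] <- w
  if (length(windows) == 0) stop("no usable training windows in fold ", k)
  log_path <- if (!is.null(cfg$out_dir))
    file.path(cfg$out_dir, sprintf("fold%d_log.jsonl", k)) else NULL
  history <- list()
  best_val <- -Inf
  best_ck <- NULL
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(windows))
    losses <- c()
    for (b0 in seq(1, length(ord), by = cfg$batch)) {
      idx <- ord[b0:min(b0 + cfg$batch - 1, length(ord))]
      loaded <- lapply(idx, function(i) {
        w <- windows[[i]]
        lw <- load_window_cached(cache, recmap[[w$clip_id]], w, cfg)
        if (cfg$augment) {
          aug <- augment_window(lw$frames, lw$masks)
          lw <- list(frames = aug$frames, masks = aug$masks)
        }
        lw
      })
      batch <- stack_windows(loaded)
      xi <- ag_tensor(clip_to_internal(batch$clips))
      ti <- clip_to_internal(batch$masks)
      ag_tape_open()
      logits <- model_forward_internal(model, xi, dim(batch$clips)[1],
                                       cfg$frames, training = TRUE)
      loss <- ag_dice_bce_loss(logits, ti)
      zero_grads(params)
      ag_backward(loss)
      adam_step(opt)
      losses <- c(losses, loss$value)
      step <- step + 1L
      if (!is.null(cfg$max_steps) && step >= cfg$max_steps) {
        done <- TRUE
        break
      }
    }
    if (epoch %% cfg$val_every != 0L && epoch < cfg$epochs && !done) {
      history[[epoch]] <- data.frame(epoch = epoch, step = step,
                                     loss = mean(losses), val_dice = NA_real_)
      next
    }
    val <- evaluate_model(model, recmap[fold$val], cfg)
    vd <- unname(val$aggregate["dice"])
    history[[epoch]] <- data.frame(epoch = epoch, step = step,
                                   loss = mean(losses), val_dice = vd)
    if (!is.null(log_path))
      cat(jsonlite::toJSON(history[[epoch]][1, ], auto_unbox = TRUE,
                           dataframe = "rows"),
          "\n", file = log_path, append = epoch > 1)
    if (cfg$verbose)
      message(sprintf("fold %d epoch %d step %d loss %.4f val dice %.4f",
                      k, epoch, step, mean(losses), vd))
    if (!is.null(cfg$target_val_dice) && vd >= cfg$target_val_dice)
      done <- TRUE
    if (vd > best_val) {
      best_val <- vd
      if (!is.null(cfg$out_dir)) {
        best_ck <- file.path(cfg$out_dir, sprintf("fold%d_best.rds", k))
        save_checkpoint(model, best_ck,
                        extra = list(epoch = epoch, val_dice = vd))
      }
    }
    if (done) break
  }
  train_eval <- evaluate_model(model, recmap[fold$train], cfg)
  list(model = model, checkpoint = best_ck,
       history = do.call(rbind, history),
       best_val_dice = best_val,
       final_loss = history[[length(history)]]$loss,
       train_dice = unname(train_eval$aggregate["dice"]))
}

# ---- evaluation -------------------------------------------------------------

predict_clip_frames <- function(model, record, cfg, cache = window_cache()) {
  wins <- make_windows(record, cfg$frames, cfg$stride)
  if (length(wins) == 0) return(NULL)
  L <- length(record$frame_paths)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  probs <- vector("list", L)
  gts <- vector("list", L)
  for (w in wins) {
    lw <- load_window_cached(cache, record, w, cfg)
    clip <- stack_windows(list(lw))
    p <- model_predict(model, clip$clips)
    for (f in seq_len(w$length)) {
      fr <- w$start + f
      if (is.null(probs[[fr]])) {  # first covering window wins
        probs[[fr]] <- p[1, f, 1, , ]
        gts[[fr]] <- lw$masks[, , 1, f]
      }
    }
  }
  list(probs = probs, gts = gts)
}

#' Evaluate a model on a clip dataset
#'
#' Each clip is covered by sliding windows of F frames; per-frame sigmoid
#' probabilities are binarized at 0.5; the clip-level metric is the mean
#' of per-frame Dice/IoU/HD95/recall, and the aggregate is the unweighted
#' mean over clips. Mean Dice is additionally stratified by the clips'
#' visual attributes.
#'
#' @param model model module (or a checkpoint path).
#' @param records clip records.
#' @param cfg a [train_config()] (frames, stride, image size, normalize).
#' @return a [metric_report()].
#' @export
evaluate_model <- function(model, records, cfg = train_config()) {
  if (is.character(model)) model <- model_from_checkpoint(model)
  rows <- list()
  attrs <- list()
  for (r in records) {
    pr <- predict_clip_frames(model, r, cfg)
    if (is.null(pr)) next
    covered <- which(!vapply(pr$probs, is.null, logical(1)))
    fm <- vapply(covered, function(f) {
      pred <- pr$probs[[f]] > 0.5
      gt <- pr$gts[[f]] > 0.5
      c(dice = dice_score(pred, gt), iou = iou_score(pred, gt),
        hd95 = as.numeric(hd95(pred, gt)), recall = recall_score(pred, gt))
    }, numeric(4))
    rows[[length(rows) + 1L]] <-
      data.frame(clip_id = r$clip_id, dice = mean(fm["dice", ]),
                 iou = mean(fm["iou", ]), hd95 = mean(fm["hd95", ]),
                 recall = mean(fm["recall", ]), stringsAsFactors = FALSE)
    attrs[[r$clip_id]] <- r$attributes
  }
  if (length(rows) == 0) stop("no clip long enough to evaluate")
  metric_report(do.call(rbind, rows),
                if (length(attrs)) attrs else NULL)
}

#' Write predicted masks as a PNG tree mirroring the input layout
#'
#' @param model model module or checkpoint path.
#' @param records clip records.
#' @param out_dir output directory (one `Pred/` folder per clip).
#' @param cfg a [train_config()].
#' @return `out_dir`, invisibly.
#' @export
predict_masks <- function(model, records, out_dir, cfg = train_config()) {
  if (is.character(model)) model <- model_from_checkpoint(model)
  for (r in records) {
    pr <- predict_clip_frames(model, r, cfg)
    if (is.null(pr)) next
    pdir <- file.path(out_dir, r$clip_id, "Pred")
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_along(pr$probs)) {
      if (is.null(pr$probs[[f]])) next
      png::writePNG((pr$probs[[f]] > 0.5) * 1,
                    file.path(pdir, sprintf("frame_%04d.png", f)))
    }
  }
  invisible(out_dir)
}

# ---- parameter verification -------------------------------------------------

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Verify the published parameter counts
#'
#' Builds the reduced backbone, the unpruned four-stage backbone and the
#' full model, and checks their trainable-parameter counts (in millions,
#' rounded half-up to 2 decimals) against 12.35, 27.82 and 21.95.
#'
#' @return data.frame with columns `component`, `parameters`, `millions`,
#'   `target`, `pass`.
#' @export
verify_params <- function() {
  cfg <- model_config(seed = 0L)
  counts <- c(
    reduced_backbone = count_parameters(build_reduced_backbone(cfg)),
    unpruned_backbone = count_parameters(build_unpruned_backbone(cfg)),
    full_model = count_parameters(build_polypnextlstm(cfg)))
  targets <- c(12.35, 27.82, 21.95)
  data.frame(component = names(counts),
             parameters = as.integer(counts),
             millions = round_half_up(counts / 1e6),
             target = targets,
             pass = round_half_up(counts / 1e6) == targets,
             row.names = NULL, stringsAsFactors = FALSE)
}
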