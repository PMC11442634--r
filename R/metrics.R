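# Training objective and evaluation metrics.
#
# Masks are logical (or 0/1 numeric) matrices; TRUE marks polyp pixels.
# Predicted masks are obtained from sigmoid probabilities at threshold 0.5.

ATTRIBUTE_IDS <- c("SI", "IB", "HO", "GH", "FM", "SO", "LO", "OCC", "OV", "SV")

as_mask <- function(m, arg) {
  if (is.null(dim(m)) || length(dim(m)) != 2L)
    stop(arg, " must be a 2-D mask")
  m > 0.5
}

check_same_dims <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("mask dims differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(gt), collapse = "x"))
  invisible(NULL)
}

#' Combined Dice + binary cross-entropy loss
#'
#' `dice_loss + bce_loss`, where the Dice term is
#' `1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)` with smoothing `s`,
#' computed per frame and averaged, and the BCE term is the mean pixelwise
#' cross-entropy. With a perfect 0/1 prediction both terms are exactly 0
#' (the smoothing constant cancels).
#'
#' @param probs numeric matrix or array in `[0, 1]`; if an array, the last
#'   dimension is the frame axis.
#' @param target mask(s) of the same shape (0/1).
#' @param smooth Dice smoothing constant (default 1).
#' @return scalar loss value (>= 0).
#' @export
dice_bce_loss <- function(probs, target, smooth = 1) {
  if (!identical(dim(probs), dim(target)) &&
      !identical(length(probs), length(target)))
    stop("probs and target shapes differ")
  p <- as.numeric(probs)
  if (any(p < 0 | p > 1)) stop("probs must lie in [0, 1]")
  t <- as.numeric(target > 0.5)
  M <- if (!is.null(dim(probs)) && length(dim(probs)) > 2L)
    dim(probs)[length(dim(probs))] else 1L
  P <- matrix(p, ncol = M)
  Tm <- matrix(t, ncol = M)
  dice <- mean(1 - (2 * colSums(P * Tm) + smooth) /
                 (colSums(P) + colSums(Tm) + smooth))
  bce <- mean(ifelse(t > 0.5, -log(p), -log1p(-p)))
  dice + bce
}

#' Dice overlap score
#'
#' `2|P&G| / (|P| + |G|)`; both masks empty returns 1.
#' @param pred,gt logical masks of identical dims.
#' @return value in `[0, 1]`.
#' @export
dice_score <- function(pred, gt) {
  pred <- as_mask(pred, "pred"); gt <- as_mask(gt, "gt")
  check_same_dims(pred, gt)
  s <- sum(pred) + sum(gt)
  if (s == 0) return(1)
  2 * sum(pred & gt) / s
}

#' Intersection-over-union score
#'
#' `|P & G| / |P | G|` (intersection over union); both masks empty
#' returns 1.
#' @inheritParams dice_score
#' @return value in `[0, 1]`.
#' @export
iou_score <- function(pred, gt) {
  pred <- as_mask(pred, "pred"); gt <- as_mask(gt, "gt")
  check_same_dims(pred, gt)
  u <- sum(pred | gt)
  if (u == 0) return(1)
  sum(pred & gt) / u
}

#' Pixel recall (sensitivity)
#'
#' `TP / (TP + FN)`; empty ground truth returns 1 by convention.
#' @inheritParams dice_score
#' @return value in `[0, 1]`.
#' @export
recall_score <- function(pred, gt) {
  pred <- as_mask(pred, "pred"); gt <- as_mask(gt, "gt")
  check_same_dims(pred, gt)
  if (sum(gt) == 0) return(1)
  sum(pred & gt) / sum(gt)
}

# Boundary pixels: mask pixels with a 4-neighbour outside the mask, or
# touching the image edge.
mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(FALSE, m[-H, , drop = FALSE])
  down <- rbind(m[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, m[, -W, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & down & left & right)
}

# Directed distances from each pixel in set A (logical matrix) to the
# nearest pixel of set B, via an exact Euclidean distance transform.
directed_boundary_distances <- function(a, b) {
  dm <- EBImage::distmap(EBImage::Image(1 - b * 1), metric = "euclidean")
  as.numeric(EBImage::imageData(dm))[as.logical(a)]
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Boundary pixel sets are extracted from both masks (4-neighbour rule,
#' image edge counts as boundary); the statistic is the maximum of the
#' 95th percentiles (linear interpolation) of the two directed Euclidean
#' distance distributions. Identical masks give 0. If both masks are
#' empty the distance is 0; if exactly one is empty the image diagonal is
#' returned as a finite sentinel, flagged with `attr(, "sentinel")`.
#'
#' @inheritParams dice_score
#' @return distance in pixels (>= 0).
#' @export
hd95 <- function(pred, gt) {
  pred <- as_mask(pred, "pred"); gt <- as_mask(gt, "gt")
  check_same_dims(pred, gt)
  ep <- sum(pred) == 0; eg <- sum(gt) == 0
  if (ep && eg) return(0)
  if (ep || eg) {
    out <- sqrt(nrow(pred)^2 + ncol(pred)^2)
    attr(out, "sentinel") <- TRUE
    return(out)
  }
  bp <- mask_boundary(pred); bg <- mask_boundary(gt)
  d_pg <- directed_boundary_distances(bp, bg)
  d_gp <- directed_boundary_distances(bg, bp)
  max(stats::quantile(d_pg, 0.95, names = FALSE, type = 7),
      stats::quantile(d_gp, 0.95, names = FALSE, type = 7))
}

#' Attribute-stratified means of per-clip scores
#'
#' Each clip contributes to the mean of every attribute it carries
#' (unweighted); attributes with no clips are absent from the result.
#'
#' @param per_clip_scores named numeric vector, clip id -> score.
#' @param clip_attributes named list, clip id -> character vector of
#'   attribute ids (subset of SI, IB, HO, GH, FM, SO, LO, OCC, OV, SV).
#' @return named numeric vector, attribute id -> mean score.
#' @export
aggregate_by_attribute <- function(per_clip_scores, clip_attributes) {
  ids <- names(per_clip_scores)
  if (is.null(ids) || !all(ids %in% names(clip_attributes)))
    stop("every clip in per_clip_scores must appear in clip_attributes")
  bad <- setdiff(unique(unlist(clip_attributes[ids])), ATTRIBUTE_IDS)
  if (length(bad))
    stop("unknown attribute id(s): ", paste(bad, collapse = ", "))
  out <- numeric(0)
  for (att in ATTRIBUTE_IDS) {
    carrying <- ids[vapply(clip_attributes[ids],
                           function(a) att %in% a, logical(1))]
    if (length(carrying))
      out[att] <- mean(per_clip_scores[carrying])
  }
  out
}

#' Assemble a metric report
#'
#' @param per_clip data.frame with columns `clip_id`, `dice`, `iou`,
#'   `hd95`, `recall` (one row per clip).
#' @param clip_attributes named list, clip id -> attribute ids; optional.
#' @return a `pnl_metric_report`: `per_clip`, `aggregate` (unweighted
#'   means over clips), `by_attribute` (mean Dice per attribute).
#' @export
metric_report <- function(per_clip, clip_attributes = NULL) {
  stopifnot(all(c("clip_id", "dice", "iou", "hd95", "recall") %in%
                  names(per_clip)))
  agg <- vapply(c("dice", "iou", "hd95", "recall"),
                function(m) mean(per_clip[[m]]), numeric(1))
  by_att <- NULL
  if (!is.null(clip_attributes)) {
    scores <- stats::setNames(per_clip$dice, per_clip$clip_id)
    by_att <- aggregate_by_attribute(scores, clip_attributes)
  }
  structure(list(per_clip = per_clip, aggregate = agg,
                 by_attribute = by_att),
            class = "pnl_metric_report")
}

#' @export
print.pnl_metric_report <- function(x, ...) {
  cat("Metric report over", nrow(x$per_clip), "clip(s)\n")
  cat(sprintf("  mean dice %.4f  iou %.4f  hd95 %.2f  recall %.4f\n",
              x$aggregate["dice"], x$aggregate["iou"],
              x$aggregate["hd95"], x$aggregate["recall"]))
  if (!is.null(x$by_attribute) && length(x$by_attribute)) {
    cat("  mean dice by attribute:\n")
    for (a in names(x$by_attribute))
      cat(sprintf("    %-4s %.4f\n", a, x$by_attribute[[a]]))
  }
  invisible(x)
}

#' Write a metric report to disk
#'
#' Per-clip rows go to `metrics.csv` (columns clip_id, dice, iou, hd95,
#' recall); the aggregate and attribute-stratified means go to
#' `metrics.json`.
#'
#' @param report a [metric_report()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_metric_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_clip[, c("clip_id", "dice", "iou", "hd95",
                                       "recall")],
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(aggregate = as.list(report$aggregate),
         by_attribute = as.list(report$by_attribute)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
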