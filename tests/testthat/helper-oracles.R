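# Independent oracles used across the suite.

pnl <- asNamespace("polypnextlstm")

# Closed-form per-layer parameter sums for the architecture, written out
# independently of the model builders.
cf_convnext_block <- function(C) {
  (49 * C + C) +            # depthwise 7x7 conv + bias
    2 * C +                 # layer norm affine
    (C * 4 * C + 4 * C) +   # 1x1 expand + bias
    (4 * C * C + C) +       # 1x1 project + bias
    C                       # per-channel residual scale
}
cf_patch_embed <- function(cin = 3, C = 96) cin * C * 16 + C + 2 * C
cf_downsample <- function(C1, C2) 2 * C1 + C1 * C2 * 4 + C2
cf_reduced_backbone <- function() {
  cf_patch_embed() + 3 * cf_convnext_block(96) + cf_downsample(96, 192) +
    3 * cf_convnext_block(192) + cf_downsample(192, 384) +
    9 * cf_convnext_block(384)
}
cf_unpruned_backbone <- function() {
  cf_reduced_backbone() + cf_downsample(384, 768) +
    3 * cf_convnext_block(768)
}
cf_biconvlstm <- function() 2 * (4 * ((384 + 192) * 192 * 9) + 4 * 192)
cf_upsample <- function(ci, co) ci * co * 4 + co
cf_double_conv <- function(ci, co) {
  ci * co * 9 + co + 2 * co + co * co * 9 + co + 2 * co
}
cf_decoder <- function() {
  cf_upsample(384, 192) + cf_double_conv(384, 192) +
    cf_upsample(192, 96) + cf_double_conv(192, 96) +
    cf_upsample(96, 48) + cf_upsample(48, 24) + (24 + 1)
}

# Brute-force directed/percentile Hausdorff from explicit pairwise
# distances (quadratic; for small masks only). Own boundary extraction.
bf_boundary_pts <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pts <- which(m, arr.ind = TRUE)
  keep <- apply(pts, 1, function(p) {
    i <- p[1]; j <- p[2]
    if (i == 1 || i == H || j == 1 || j == W) return(TRUE)
    !(m[i - 1, j] && m[i + 1, j] && m[i, j - 1] && m[i, j + 1])
  })
  pts[keep, , drop = FALSE]
}

bf_directed <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2)), numeric(1))
}

bf_hd95 <- function(pred, gt) {
  A <- bf_boundary_pts(pred); B <- bf_boundary_pts(gt)
  max(quantile(bf_directed(A, B), 0.95, names = FALSE),
      quantile(bf_directed(B, A), 0.95, names = FALSE))
}

bf_hausdorff <- function(pred, gt) {
  A <- bf_boundary_pts(pred); B <- bf_boundary_pts(gt)
  max(max(bf_directed(A, B)), max(bf_directed(B, A)))
}

# Random blob-ish mask with a bounded number of boundary pixels.
random_small_mask <- function(H = 24, W = 24) {
  m <- matrix(FALSE, H, W)
  cy <- runif(1, 6, H - 6); cx <- runif(1, 6, W - 6)
  r <- runif(1, 2, 5)
  y <- matrix(seq_len(H), H, W); x <- matrix(seq_len(W), H, W, byrow = TRUE)
  m[(y - cy)^2 + (x - cx)^2 <= r^2] <- TRUE
  m
}

# A one-clip synthetic dataset on disk; returns its scan_dataset records.
make_single_clip_dataset <- function(dir, n_frames = 5, size = c(64, 64),
                                     seed = 11) {
  spec <- synth_clip_spec(n_frames = n_frames, image_size = size,
                          velocity = c(0.5, 0.7), seed = seed)
  write_clip(render_clip(spec), file.path(dir, "case001_1"))
  utils::write.csv(data.frame(clip_id = "case001_1",
                              polyp_case_id = "case001", attributes = ""),
                   file.path(dir, "attributes.csv"), row.names = FALSE)
  scan_dataset(dir)
}
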