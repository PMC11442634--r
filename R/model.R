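# PolypNextLSTM: pruned ConvNext-Tiny encoder, bidirectional ConvLSTM
# temporal bottleneck, UNet-style decoder.
#
# Clip batches are arrays of dim c(B, F, C, H, W). Internally the batch and
# frame axes are flattened (frame-major: n = b + B*(f-1)) and maps are held
# as c(H, W, C, B*F); only the temporal fusion module sees the frame axis.

#' Model configuration
#'
#' Captures the architecture hyperparameters. Defaults reproduce the
#' published network: three encoder stages of (3, 3, 9) ConvNext blocks at
#' widths (96, 192, 384), a bidirectional ConvLSTM with hidden size 192
#' (so the concatenated forward/backward output restores 384 channels),
#' and a decoder tail of widths (48, 24) before the 1-channel output.
#'
#' @param in_channels input image channels (3 for RGB).
#' @param stage_widths encoder stage widths, length 3.
#' @param stage_depths ConvNext blocks per stage, must be c(3, 3, 9).
#' @param lstm_hidden ConvLSTM hidden channels; must equal
#'   `stage_widths[3] / 2`.
#' @param lstm_kernel,lstm_padding ConvLSTM gate convolution geometry.
#' @param decoder_tail_widths channel widths of the two skip-free decoder
#'   upsampling steps.
#' @param layer_scale_init initial value of the per-channel residual scale
#'   in each ConvNext block.
#' @param pretrained_backbone reserved flag; no weights are downloaded and
#'   random initialization is the default.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   before parameter initialization by the builders.
#' @return a `pnl_config` list.
#' @export
model_config <- function(in_channels = 3L,
                         stage_widths = c(96L, 192L, 384L),
                         stage_depths = c(3L, 3L, 9L),
                         lstm_hidden = 192L,
                         lstm_kernel = 3L,
                         lstm_padding = 1L,
                         decoder_tail_widths = c(48L, 24L),
                         layer_scale_init = 1e-6,
                         pretrained_backbone = FALSE,
                         seed = NULL) {
  if (!identical(as.integer(stage_depths), c(3L, 3L, 9L)))
    stop("stage_depths must be c(3, 3, 9)")
  if (length(stage_widths) != 3L)
    stop("stage_widths must have length 3")
  if (lstm_hidden * 2L != stage_widths[3])
    stop("lstm_hidden must be stage_widths[3] / 2 so the concatenated ",
         "bidirectional output restores ", stage_widths[3], " channels")
  structure(list(in_channels = as.integer(in_channels),
                 stage_widths = as.integer(stage_widths),
                 stage_depths = as.integer(stage_depths),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_kernel = as.integer(lstm_kernel),
                 lstm_padding = as.integer(lstm_padding),
                 decoder_tail_widths = as.integer(decoder_tail_widths),
                 layer_scale_init = layer_scale_init,
                 pretrained_backbone = isTRUE(pretrained_backbone),
                 seed = seed),
            class = "pnl_config")
}

maybe_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

make_stage <- function(width, depth, layer_scale_init) {
  blocks <- lapply(seq_len(depth), function(i)
    layer_convnext_block(width, layer_scale_init))
  names(blocks) <- paste0("block", seq_len(depth))
  pnl_module("stage", children = blocks)
}

stage_forward <- function(stage, x, training = FALSE) {
  for (b in stage$children) x <- module_forward(b, x, training)
  x
}

#' Build the pruned three-stage ConvNext-Tiny encoder
#'
#' Patch embedding (4x4 stride-4 conv, 3 -> 96, + layer norm), then three
#' stages of (3, 3, 9) ConvNext blocks at widths (96, 192, 384) with
#' norm + 2x2 stride-2 conv downsampling between stages. The fourth stage
#' and all classification layers of the original ConvNext-Tiny are
#' removed; the trainable parameter count rounds to 12.35 million.
#'
#' @param cfg a [model_config()].
#' @return an encoder module.
#' @export
build_reduced_backbone <- function(cfg = model_config()) {
  maybe_seed(cfg)
  w <- cfg$stage_widths
  d <- cfg$stage_depths
  ls <- cfg$layer_scale_init
  pnl_module("encoder",
             children = list(
               patch_embed = layer_patch_embed(cfg$in_channels, w[1]),
               stage1 = make_stage(w[1], d[1], ls),
               down1 = layer_downsample(w[1], w[2]),
               stage2 = make_stage(w[2], d[2], ls),
               down2 = layer_downsample(w[2], w[3]),
               stage3 = make_stage(w[3], d[3], ls)),
             cfg = list(widths = w))
}

#' Build the unpruned four-stage ConvNext-Tiny (no classification head)
#'
#' The original (3, 3, 9, 3) layout with a fourth stage at width 768,
#' kept only to verify the published 27.82-million-parameter count that
#' the pruning reduces to 12.35 million.
#'
#' @param cfg a [model_config()].
#' @return an encoder module with a fourth stage.
#' @export
build_unpruned_backbone <- function(cfg = model_config()) {
  enc <- build_reduced_backbone(cfg)
  w4 <- cfg$stage_widths[3] * 2L
  enc$children$down3 <- layer_downsample(cfg$stage_widths[3], w4)
  enc$children$stage4 <- make_stage(w4, 3L, cfg$layer_scale_init)
  enc
}

# Run the encoder on a flattened batch; returns the three-scale pyramid
# (skips at /4 and /8, bottleneck at /16). A fourth stage, if present,
# adds a `final` map at /32.
encoder_forward <- function(enc, x, training = FALSE) {
  d <- dim(x$value)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("encoder: spatial dims ", d[1], "x", d[2],
         " must be divisible by 16")
  h <- module_forward(enc$children$patch_embed, x, training)
  skip4 <- stage_forward(enc$children$stage1, h, training)
  h <- module_forward(enc$children$down1, skip4, training)
  skip8 <- stage_forward(enc$children$stage2, h, training)
  h <- module_forward(enc$children$down2, skip8, training)
  bottleneck <- stage_forward(enc$children$stage3, h, training)
  out <- list(skip4 = skip4, skip8 = skip8, bottleneck = bottleneck)
  if (!is.null(enc$children$down3)) {
    h <- module_forward(enc$children$down3, bottleneck, training)
    out$final <- stage_forward(enc$children$stage4, h, training)
  }
  out
}

#' Build the bidirectional ConvLSTM fusion module
#'
#' One ConvLSTM cell (input 384, hidden 192, 3x3 kernel, zero padding 1)
#' scans the frames first-to-last, a second independent cell scans
#' last-to-first; per frame the two 192-channel hidden states are
#' concatenated (forward half first) to restore 384 channels. Initial
#' hidden and cell states are zeros.
#'
#' @param cfg a [model_config()].
#' @return a fusion module.
#' @export
build_biconvlstm <- function(cfg = model_config()) {
  cin <- cfg$stage_widths[3]
  pnl_module("biconvlstm",
             children = list(
               fwd = layer_convlstm_cell(cin, cfg$lstm_hidden,
                                         cfg$lstm_kernel, cfg$lstm_padding),
               bwd = layer_convlstm_cell(cin, cfg$lstm_hidden,
                                         cfg$lstm_kernel, cfg$lstm_padding)),
             cfg = list(cin = cin, chidden = cfg$lstm_hidden))
}

# Fusion on the flattened (frame-major) bottleneck. Returns the fused map
# in the same layout.
biconvlstm_forward_internal <- function(m, x, B, F, training = FALSE) {
  d <- dim(x$value)
  if (d[3] != m$cfg$cin)
    stop("biconvlstm: expected ", m$cfg$cin, " channels, got ", d[3])
  if (F < 1L) stop("biconvlstm: empty input (F = 0)")
  ch <- m$cfg$chidden
  zeros <- ag_tensor(array(0, c(d[1], d[2], ch, B)))
  frames <- lapply(seq_len(F), function(f)
    ag_gather_n(x, (f - 1L) * B + seq_len(B)))
  h <- zeros; cs <- zeros
  h_fwd <- vector("list", F)
  for (f in seq_len(F)) {
    st <- convlstm_step(m$children$fwd, frames[[f]], h, cs, training)
    h <- st$h; cs <- st$c
    h_fwd[[f]] <- st$h
  }
  h <- zeros; cs <- zeros
  h_bwd <- vector("list", F)
  for (f in rev(seq_len(F))) {
    st <- convlstm_step(m$children$bwd, frames[[f]], h, cs, training)
    h <- st$h; cs <- st$c
    h_bwd[[f]] <- st$h
  }
  fused <- lapply(seq_len(F), function(f)
    ag_concat_c(h_fwd[[f]], h_bwd[[f]]))
  ag_concat_n(fused)
}

#' Apply the bidirectional ConvLSTM to a clip-shaped feature tensor
#'
#' @param m fusion module from [build_biconvlstm()].
#' @param x numeric array of dim c(B, F, C, h, w) with C = 384.
#' @return numeric array of the same shape.
#' @export
biconvlstm_apply <- function(m, x) {
  d <- dim(x)
  xi <- ag_tensor(clip_to_internal(x))
  y <- biconvlstm_forward_internal(m, xi, d[1], d[2])
  internal_to_clip(y$value, d[1], d[2])
}

#' Build the UNet-style decoder
#'
#' Transposed-conv upsampling 384->192 and 192->96 with skip
#' concatenation and DoubleConv merging, then a skip-free tail
#' 96->48->24 and a 1x1 output convolution to one channel.
#'
#' @param cfg a [model_config()].
#' @return a decoder module.
#' @export
build_decoder <- function(cfg = model_config()) {
  w <- cfg$stage_widths
  tw <- cfg$decoder_tail_widths
  pnl_module("decoder",
             children = list(
               up1 = layer_convtr2x2(w[3], w[2]),
               dc1 = layer_double_conv(w[3], w[2]),
               up2 = layer_convtr2x2(w[2], w[1]),
               dc2 = layer_double_conv(w[2], w[1]),
               up3 = layer_convtr2x2(w[1], tw[1]),
               up4 = layer_convtr2x2(tw[1], tw[2]),
               out = layer_conv2d(1L, 1L, tw[2], 1L, init = "he")))
}

check_skip <- function(x, skip, stage) {
  dx <- dim(x$value); ds <- dim(skip$value)
  if (dx[1] != ds[1] || dx[2] != ds[2])
    stop("decoder ", stage, ": upsampled map is ", dx[1], "x", dx[2],
         " but the skip connection is ", ds[1], "x", ds[2])
  invisible(NULL)
}

decoder_forward <- function(dec, pyr, fused, training = FALSE) {
  x <- module_forward(dec$children$up1, fused, training)
  check_skip(x, pyr$skip8, "up1")
  x <- ag_concat_c(x, pyr$skip8)
  x <- module_forward(dec$children$dc1, x, training)
  x <- module_forward(dec$children$up2, x, training)
  check_skip(x, pyr$skip4, "up2")
  x <- ag_concat_c(x, pyr$skip4)
  x <- module_forward(dec$children$dc2, x, training)
  x <- module_forward(dec$children$up3, x, training)
  x <- module_forward(dec$children$up4, x, training)
  module_forward(dec$children$out, x, training)
}

#' Build the full PolypNextLSTM model
#'
#' Encoder + bidirectional ConvLSTM bottleneck + decoder; the trainable
#' parameter count rounds to 21.95 million.
#'
#' @param cfg a [model_config()].
#' @return a model module.
#' @export
build_polypnextlstm <- function(cfg = model_config()) {
  maybe_seed(cfg)
  m <- pnl_module("polypnextlstm",
                  children = list(encoder = build_reduced_backbone(cfg),
                                  fusion = build_biconvlstm(cfg),
                                  decoder = build_decoder(cfg)))
  m$model_cfg <- cfg
  m
}

# ---- clip layout conversion -------------------------------------------------

# (B, F, C, H, W) -> internal (H, W, C, B*F), frame-major.
clip_to_internal <- function(x) {
  d <- dim(x)
  xi <- aperm(x, c(4, 5, 3, 1, 2))
  dim(xi) <- c(d[4], d[5], d[3], d[1] * d[2])
  xi
}

# internal (H, W, C, B*F) -> (B, F, C, H, W).
internal_to_clip <- function(xi, B, F) {
  d <- dim(xi)
  dim(xi) <- c(d[1], d[2], d[3], B, F)
  aperm(xi, c(4, 5, 3, 1, 2))
}

validate_clip <- function(clip) {
  d <- dim(clip)
  if (length(d) != 5L)
    stop("clip must be a 5-D array (B, F, C, H, W); got ",
         length(d), " dims")
  if (d[3] != 3L)
    stop("clip must have 3 channels; got ", d[3])
  if (d[2] < 1L) stop("clip must contain at least one frame")
  if (d[4] %% 16L != 0L)
    stop("clip height ", d[4], " is not divisible by 16")
  if (d[5] %% 16L != 0L)
    stop("clip width ", d[5], " is not divisible by 16")
  d
}

# Full forward on the internal layout; returns ag logits (H, W, 1, B*F).
model_forward_internal <- function(model, xi, B, F, training = FALSE) {
  pyr <- encoder_forward(model$children$encoder, xi, training)
  fused <- biconvlstm_forward_internal(model$children$fusion,
                                       pyr$bottleneck, B, F, training)
  decoder_forward(model$children$decoder, pyr, fused, training)
}

#' Run the model on a clip batch
#'
#' The encoder and decoder process the flattened B*F batch of frames
#' independently; only the ConvLSTM bottleneck sees the temporal axis.
#' One pre-sigmoid logit map is produced per input frame.
#'
#' @param model module from [build_polypnextlstm()].
#' @param clip numeric array of dim c(B, F, 3, H, W), H and W divisible
#'   by 16.
#' @return numeric array of logits, dim c(B, F, 1, H, W).
#' @export
model_forward <- function(model, clip) {
  d <- validate_clip(clip)
  xi <- ag_tensor(clip_to_internal(clip))
  y <- model_forward_internal(model, xi, d[1], d[2], training = FALSE)
  internal_to_clip(y$value, d[1], d[2])
}

#' Predict polyp probability masks for a clip batch
#'
#' @inheritParams model_forward
#' @return array of sigmoid probabilities, dim c(B, F, 1, H, W).
#' @export
model_predict <- function(model, clip) {
  p <- stats::plogis(model_forward(model, clip))
  dim(p) <- c(dim(clip)[1:2], 1L, dim(clip)[4:5])
  p
}

# ---- checkpointing ----------------------------------------------------------

#' Save model weights (and config) to a single file
#'
#' Weights are keyed by module path so they can be restored into a freshly
#' built model of the same configuration.
#'
#' @param model model module.
#' @param path output file.
#' @param extra optional named list stored alongside the weights.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  params <- collect_parameters(model)
  bn <- collect_bn_state(model)
  obj <- list(config = model$model_cfg,
              params = lapply(params, function(p) p$value),
              bn = lapply(bn, function(e) list(mu = e$mu, var = e$var)),
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Restore weights saved by [save_checkpoint()] into a model
#'
#' @param model model module built with a matching configuration; modified
#'   in place (parameters are environments).
#' @param path checkpoint file.
#' @return the model, invisibly.
#' @export
load_checkpoint <- function(model, path) {
  obj <- readRDS(path)
  params <- collect_parameters(model)
  missing <- setdiff(names(params), names(obj$params))
  if (length(missing))
    stop("checkpoint is missing parameters: ",
         paste(utils::head(missing, 3), collapse = ", "))
  for (nm in names(params)) {
    saved <- obj$params[[nm]]
    if (length(saved) != length(params[[nm]]$value))
      stop("checkpoint parameter ", nm, " has length ", length(saved),
           ", model expects ", length(params[[nm]]$value))
    params[[nm]]$value <- saved
  }
  bn <- collect_bn_state(model)
  for (nm in names(bn)) {
    if (!is.null(obj$bn[[nm]])) {
      bn[[nm]]$mu <- obj$bn[[nm]]$mu
      bn[[nm]]$var <- obj$bn[[nm]]$var
    }
  }
  invisible(model)
}

#' Rebuild a model from a checkpoint file
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return a model with restored weights.
#' @export
model_from_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  if (is.null(cfg)) cfg <- model_config()
  model <- build_polypnextlstm(cfg)
  load_checkpoint(model, path)
  model
}
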