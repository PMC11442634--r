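# Network layers. A module is a plain list with fields:
#   type     - dispatch string for module_forward()
#   params   - named list of ag_tensor parameters
#   children - named list of sub-modules
#   cfg      - layer hyperparameters
# Parameters are environments, so checkpoint loading mutates in place.

pnl_module <- function(type, params = list(), children = list(), cfg = list()) {
  structure(list(type = type, params = params, children = children, cfg = cfg),
            class = "pnl_module")
}

# Truncated-normal init (sd 0.02, clipped at 2 sd), the ConvNext convention.
init_trunc_normal <- function(dims, sd = 0.02) {
  v <- stats::rnorm(prod(dims), 0, sd)
  v <- pmin(pmax(v, -2 * sd), 2 * sd)
  array(v, dims)
}

# He (Kaiming) init for ReLU-family layers.
init_he <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

layer_conv2d <- function(kh, kw, cin, cout, stride = 1L, pad = 0L,
                         init = c("trunc", "he")) {
  init <- match.arg(init)
  w <- if (init == "trunc") init_trunc_normal(c(kh, kw, cin, cout))
       else init_he(c(kh, kw, cin, cout), kh * kw * cin)
  pnl_module("conv2d",
             params = list(w = ag_param(w), b = ag_param(numeric(cout))),
             cfg = list(stride = stride, pad = pad))
}

layer_dwconv2d <- function(k, c, pad, init = "trunc") {
  pnl_module("dwconv2d",
             params = list(w = ag_param(init_trunc_normal(c(k, k, c))),
                           b = ag_param(numeric(c))),
             cfg = list(pad = pad))
}

layer_convtr2x2 <- function(cin, cout) {
  pnl_module("convtr2x2",
             params = list(w = ag_param(init_he(c(2, 2, cin, cout), 4 * cin)),
                           b = ag_param(numeric(cout))))
}

layer_layernorm <- function(c, eps = 1e-6) {
  pnl_module("layernorm",
             params = list(gamma = ag_param(rep(1, c)),
                           beta = ag_param(numeric(c))),
             cfg = list(eps = eps))
}

layer_batchnorm <- function(c, eps = 1e-5, momentum = 0.1) {
  m <- pnl_module("batchnorm",
                  params = list(gamma = ag_param(rep(1, c)),
                                beta = ag_param(numeric(c))),
                  cfg = list(eps = eps, momentum = momentum))
  # running statistics live in an environment so they update in place
  m$state <- new.env(parent = emptyenv())
  m$state$mu <- numeric(c)
  m$state$var <- rep(1, c)
  m
}

#' ConvNext block
#'
#' Residual block: depthwise 7x7 conv (pad 3) -> channels-first layer norm
#' -> 1x1 conv C->4C -> GELU -> 1x1 conv 4C->C -> learnable per-channel
#' scale -> add input. Spatial dims unchanged.
#' @keywords internal
layer_convnext_block <- function(c, layer_scale_init = 1e-6) {
  pnl_module("convnext_block",
             children = list(
               dw = layer_dwconv2d(7L, c, pad = 3L),
               norm = layer_layernorm(c),
               pw1 = layer_conv2d(1L, 1L, c, 4L * c),
               pw2 = layer_conv2d(1L, 1L, 4L * c, c)),
             params = list(scale = ag_param(rep(layer_scale_init, c))),
             cfg = list(width = c))
}

#' Patch embedding: 4x4 stride-4 conv (3 -> width) + channel layer norm
#' @keywords internal
layer_patch_embed <- function(cin = 3L, cout = 96L) {
  pnl_module("patch_embed",
             children = list(conv = layer_conv2d(4L, 4L, cin, cout,
                                                 stride = 4L, pad = 0L),
                             norm = layer_layernorm(cout)))
}

# Downsampling between encoder stages: layer norm then 2x2 stride-2 conv.
layer_downsample <- function(cin, cout) {
  pnl_module("downsample",
             children = list(norm = layer_layernorm(cin),
                             conv = layer_conv2d(2L, 2L, cin, cout,
                                                 stride = 2L, pad = 0L)))
}

# Decoder DoubleConv: two 3x3 conv + batch norm + ReLU, first conv halves
# the channel count.
layer_double_conv <- function(cin, cout) {
  pnl_module("double_conv",
             children = list(
               conv1 = layer_conv2d(3L, 3L, cin, cout, pad = 1L, init = "he"),
               bn1 = layer_batchnorm(cout),
               conv2 = layer_conv2d(3L, 3L, cout, cout, pad = 1L, init = "he"),
               bn2 = layer_batchnorm(cout)))
}

# One ConvLSTM cell: all four gates from a single 3x3 convolution over the
# channel-concatenated [input, hidden]; biases included, no peephole
# connections; zero initial states.
layer_convlstm_cell <- function(cin, chidden, k = 3L, pad = 1L) {
  pnl_module("convlstm_cell",
             children = list(
               gates = layer_conv2d(k, k, cin + chidden, 4L * chidden,
                                    pad = pad, init = "he")),
             cfg = list(cin = cin, chidden = chidden))
}

# ---- forward dispatch -------------------------------------------------------

module_forward <- function(m, x, training = FALSE) {
  switch(m$type,
    conv2d = ag_conv2d(x, m$params$w, m$params$b, m$cfg$stride, m$cfg$pad),
    dwconv2d = ag_dwconv2d(x, m$params$w, m$params$b, m$cfg$pad),
    convtr2x2 = ag_convtr2x2(x, m$params$w, m$params$b),
    layernorm = ag_layernorm_cf(x, m$params$gamma, m$params$beta, m$cfg$eps),
    batchnorm = forward_batchnorm(m, x, training),
    convnext_block = forward_convnext_block(m, x, training),
    patch_embed = forward_patch_embed(m, x, training),
    downsample = {
      h <- module_forward(m$children$norm, x, training)
      module_forward(m$children$conv, h, training)
    },
    double_conv = forward_double_conv(m, x, training),
    stop("module_forward: unknown module type ", m$type)
  )
}

forward_batchnorm <- function(m, x, training) {
  if (training) {
    nd <- ag_batchnorm_train(x, m$params$gamma, m$params$beta, m$cfg$eps)
    mom <- m$cfg$momentum
    m$state$mu <- (1 - mom) * m$state$mu + mom * nd$bn_stats$mu
    m$state$var <- (1 - mom) * m$state$var + mom * nd$bn_stats$var
    nd
  } else {
    ag_batchnorm_eval(x, m$params$gamma, m$params$beta,
                      m$state$mu, m$state$var, m$cfg$eps)
  }
}

forward_convnext_block <- function(m, x, training) {
  cin <- dim(x$value)[3]
  if (cin != m$cfg$width)
    stop("convnext_block: input has ", cin, " channels, block width is ",
         m$cfg$width)
  h <- module_forward(m$children$dw, x, training)
  h <- module_forward(m$children$norm, h, training)
  h <- module_forward(m$children$pw1, h, training)
  h <- ag_gelu(h)
  h <- module_forward(m$children$pw2, h, training)
  h <- ag_scale_channels(h, m$params$scale)
  ag_add(x, h)
}

forward_patch_embed <- function(m, x, training) {
  d <- dim(x$value)
  if (d[1] %% 4L != 0L)
    stop("patch_embed: height ", d[1], " is not divisible by 4")
  if (d[2] %% 4L != 0L)
    stop("patch_embed: width ", d[2], " is not divisible by 4")
  h <- module_forward(m$children$conv, x, training)
  module_forward(m$children$norm, h, training)
}

forward_double_conv <- function(m, x, training) {
  h <- module_forward(m$children$conv1, x, training)
  h <- forward_batchnorm(m$children$bn1, h, training)
  h <- ag_relu(h)
  h <- module_forward(m$children$conv2, h, training)
  h <- forward_batchnorm(m$children$bn2, h, training)
  ag_relu(h)
}

# One ConvLSTM step. Gate order: input, forget, output, candidate.
convlstm_step <- function(cell, x, h, c_state, training = FALSE) {
  ch <- cell$cfg$chidden
  gates <- module_forward(cell$children$gates, ag_concat_c(x, h), training)
  i <- ag_sigmoid(ag_slice_c(gates, 1L, ch))
  f <- ag_sigmoid(ag_slice_c(gates, ch + 1L, 2L * ch))
  o <- ag_sigmoid(ag_slice_c(gates, 2L * ch + 1L, 3L * ch))
  g <- ag_tanh(ag_slice_c(gates, 3L * ch + 1L, 4L * ch))
  c_new <- ag_add(ag_mul(f, c_state), ag_mul(i, g))
  h_new <- ag_mul(o, ag_tanh(c_new))
  list(h = h_new, c = c_new)
}

# ---- parameter bookkeeping --------------------------------------------------

#' Count trainable parameters
#'
#' @param m a module (any sub-tree of the model).
#' @return integer number of trainable scalars.
#' @export
count_parameters <- function(m) {
  if (is.null(m)) return(0L)
  n <- sum(vapply(m$params, function(p) length(p$value), numeric(1)))
  for (ch in m$children) n <- n + count_parameters(ch)
  as.integer(n)
}

# Flatten all parameters to a named list "path/leaf" -> ag_tensor.
collect_parameters <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params))
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$children))
    out <- c(out, collect_parameters(m$children[[nm]],
                                     paste0(prefix, nm, "/")))
  out
}

# Collect batch-norm running-stat environments keyed by path.
collect_bn_state <- function(m, prefix = "") {
  out <- list()
  if (identical(m$type, "batchnorm")) out[[paste0(prefix, ".bn")]] <- m$state
  for (nm in names(m$children))
    out <- c(out, collect_bn_state(m$children[[nm]], paste0(prefix, nm, "/")))
  out
}

#' Per-submodule parameter summary
#'
#' @param m a module.
#' @param name label for the root row.
#' @return data.frame with columns `module` and `n_params`.
#' @export
parameter_summary <- function(m, name = "model") {
  rows <- data.frame(module = name, n_params = count_parameters(m),
                     stringsAsFactors = FALSE)
  for (nm in names(m$children)) {
    ch <- parameter_summary(m$children[[nm]], paste0(name, "/", nm))
    rows <- rbind(rows, ch)
  }
  rows
}

# Zero accumulated gradients on all parameters.
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
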