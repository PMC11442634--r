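# Minimal reverse-mode automatic differentiation over 4-D arrays.
#
# Feature maps are numeric arrays of dim c(H, W, C, N); N is the flattened
# batch*frame axis. A "tensor" is an environment holding a value and, after
# the backward pass, a gradient. While a tape is open every op appends a
# node with a vector-Jacobian closure; with no tape open ops are plain
# forward computations (used for evaluation, where no graph is kept).

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

#' Wrap an array as an autodiff tensor
#'
#' @param value numeric array (any dim).
#' @param requires_grad logical; `TRUE` for trainable parameters.
#' @return an `ag_tensor` environment with fields `value` and `grad`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$requires_grad <- requires_grad
  nd$parents <- NULL
  nd$vjp <- NULL
  class(nd) <- "ag_tensor"
  nd
}

#' @keywords internal
ag_param <- function(value) ag_tensor(value, requires_grad = TRUE)

is_ag <- function(x) inherits(x, "ag_tensor")

#' Open a gradient tape
#'
#' Subsequent ops record the graph until [ag_tape_close()] is called.
#' @keywords internal
ag_tape_open <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  .ag$tape <- t
  invisible(t)
}

#' @keywords internal
ag_tape_close <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

ag_recording <- function() !is.null(.ag$tape)

# Create an op node. `vjp(grad)` must return a list of gradients aligned
# with `parents` (NULL entries allowed).
ag_op <- function(value, parents, vjp) {
  nd <- ag_tensor(value)
  t <- .ag$tape
  if (!is.null(t)) {
    nd$parents <- parents
    nd$vjp <- vjp
    n <- t$n + 1L
    if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[n]] <- nd
    t$n <- n
  }
  nd
}

#' Reverse-pass through the recorded tape
#'
#' Accumulates gradients into every reachable tensor with
#' `requires_grad = TRUE`. The tape is consumed and closed.
#' @param loss scalar-valued `ag_tensor`.
#' @keywords internal
ag_backward <- function(loss) {
  t <- .ag$tape
  if (is.null(t)) stop("ag_backward: no tape is open")
  loss$grad <- 1
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
    nd$grad <- NULL
  }
  ag_tape_close()
  invisible(NULL)
}

# ---- primitive ops ----------------------------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  y <- cpp_conv2d_fw(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  ag_op(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bw(x$value, w$value, g, as.integer(stride), as.integer(pad))
    list(r$dx, r$dw, r$db)
  })
}

ag_dwconv2d <- function(x, w, b, pad) {
  y <- cpp_dwconv2d_fw(x$value, w$value, b$value, as.integer(pad))
  ag_op(y, list(x, w, b), function(g) {
    r <- cpp_dwconv2d_bw(x$value, w$value, g, as.integer(pad))
    list(r$dx, r$dw, r$db)
  })
}

ag_convtr2x2 <- function(x, w, b) {
  y <- cpp_convtr2x2_fw(x$value, w$value, b$value)
  ag_op(y, list(x, w, b), function(g) {
    r <- cpp_convtr2x2_bw(x$value, w$value, g)
    list(r$dx, r$dw, r$db)
  })
}

# Channels-first layer norm (normalizes over C at each spatial position).
ag_layernorm_cf <- function(x, gamma, beta, eps = 1e-6) {
  r <- cpp_layernorm_cf_fw(x$value, gamma$value, beta$value, eps)
  ag_op(r$y, list(x, gamma, beta), function(g) {
    b <- cpp_layernorm_cf_bw(g, r$xhat, r$invstd, gamma$value)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

# Batch norm over (H, W, N) per channel; training-mode statistics. The
# running-stat update is handled by the owning layer.
ag_batchnorm_train <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]
  m <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  val <- aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  nd <- ag_op(val, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    dxh <- sweep(gm, 2, gamma$value, `*`)
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat)
    dxm <- sweep(sweep(dxh, 2, m1) - sweep(xhat, 2, m2, `*`), 2, invstd, `*`)
    dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    list(dx, colSums(gm * xhat), colSums(gm))
  })
  attr(nd$value, "bn_mu") <- NULL
  nd$bn_stats <- list(mu = mu, var = v)
  nd
}

ag_batchnorm_eval <- function(x, gamma, beta, mu, v, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]
  scale <- gamma$value / sqrt(v + eps)
  shift <- beta$value - mu * scale
  per <- rep(rep(scale, each = d[1] * d[2]), times = d[4])
  off <- rep(rep(shift, each = d[1] * d[2]), times = d[4])
  y <- x$value * per + off
  dim(y) <- d
  ag_op(y, list(x, gamma, beta), function(g) {
    xm <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(v + eps), `/`)
    dx <- g * per
    dim(dx) <- d
    list(dx, colSums(gm * xhat), colSums(gm))
  })
}

ag_relu <- function(x) {
  y <- pmax(x$value, 0)
  dim(y) <- dim(x$value)
  ag_op(y, list(x), function(g) list(g * (x$value > 0)))
}

# Exact (erf) GELU, the ConvNext activation.
ag_gelu <- function(x) {
  v <- x$value
  y <- v * stats::pnorm(v)
  dim(y) <- dim(v)
  ag_op(y, list(x), function(g) list(g * (stats::pnorm(v) + v * stats::dnorm(v))))
}

ag_sigmoid <- function(x) {
  y <- stats::plogis(x$value)
  dim(y) <- dim(x$value)
  ag_op(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_tanh <- function(x) {
  y <- tanh(x$value)
  dim(y) <- dim(x$value)
  ag_op(y, list(x), function(g) list(g * (1 - y * y)))
}

ag_add <- function(a, b) {
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  ag_op(a$value * b$value, list(a, b),
        function(g) list(g * b$value, g * a$value))
}

# Per-channel multiplicative scale (ConvNext layer scale). gamma length C.
ag_scale_channels <- function(x, gamma) {
  d <- dim(x$value)
  per <- rep(rep(gamma$value, each = d[1] * d[2]), times = d[4])
  y <- x$value * per
  dim(y) <- d
  ag_op(y, list(x, gamma), function(g) {
    dx <- g * per
    dim(dx) <- d
    s <- colSums(matrix(g * x$value, ncol = d[3] * d[4]))
    dgamma <- rowSums(matrix(s, nrow = d[3]))
    list(dx, dgamma)
  })
}

# Concatenate along the channel axis.
ag_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  if (any(da[c(1, 2, 4)] != db[c(1, 2, 4)]))
    stop("concat_c: spatial/batch dims differ: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"))
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  ag_op(y, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

ag_slice_c <- function(x, from, to) {
  d <- dim(x$value)
  y <- x$value[, , from:to, , drop = FALSE]
  ag_op(y, list(x), function(g) {
    dx <- array(0, d)
    dx[, , from:to, ] <- g
    list(dx)
  })
}

# Gather along the flattened batch axis (used to slice/reassemble frames).
ag_gather_n <- function(x, idx) {
  d <- dim(x$value)
  y <- x$value[, , , idx, drop = FALSE]
  ag_op(y, list(x), function(g) {
    dx <- array(0, d)
    acc <- dx[, , , idx, drop = FALSE]
    dx[, , , idx] <- acc + g
    list(dx)
  })
}

# Concatenate a list of tensors along the batch axis.
ag_concat_n <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  ns <- vapply(ds, function(d) d[4], numeric(1))
  d1 <- ds[[1]]
  y <- array(0, c(d1[1], d1[2], d1[3], sum(ns)))
  at <- 0L
  for (x in xs) {
    n <- dim(x$value)[4]
    y[, , , at + seq_len(n)] <- x$value
    at <- at + n
  }
  offs <- cumsum(c(0, ns))
  ag_op(y, xs, function(g) {
    lapply(seq_along(xs), function(j) {
      g[, , , offs[j] + seq_len(ns[j]), drop = FALSE]
    })
  })
}

#' Combined Dice + binary cross-entropy loss on logits
#'
#' The Dice term is computed per frame with additive smoothing and averaged
#' over the flattened batch*frame axis; the BCE term is the mean pixelwise
#' cross-entropy, evaluated in a numerically stable form from logits. The
#' two terms are summed with equal weight.
#'
#' @param logits `ag_tensor`, dim c(H, W, 1, M) (pre-sigmoid).
#' @param target numeric/logical array of the same dim, values 0/1.
#' @param smooth additive smoothing constant in the Dice term (default 1).
#' @return scalar `ag_tensor`; its `value` is `dice_loss + bce_loss`.
#' @keywords internal
ag_dice_bce_loss <- function(logits, target, smooth = 1) {
  z <- logits$value
  d <- dim(z)
  M <- d[4]
  tt <- as.numeric(target)
  p <- stats::plogis(as.numeric(z))
  npix <- length(p)
  P <- matrix(p, ncol = M)
  Tm <- matrix(tt, ncol = M)
  Sp <- colSums(P); St <- colSums(Tm); Spt <- colSums(P * Tm)
  denom <- Sp + St + smooth
  dice_loss <- mean(1 - (2 * Spt + smooth) / denom)
  za <- as.numeric(z)
  bce <- mean(pmax(za, 0) - za * tt + log1p(exp(-abs(za))))
  ag_op(dice_loss + bce, list(logits), function(g) {
    # d(dice)/dp per frame, then chain through the sigmoid
    num <- 2 * Spt + smooth
    ddice_dp <- sweep(sweep(-2 * Tm, 2, denom, `*`), 2, num, `+`) /
      rep(denom^2, each = nrow(P)) / M
    dz_dice <- as.numeric(ddice_dp) * p * (1 - p)
    dz_bce <- (p - tt) / npix
    dz <- g * (dz_dice + dz_bce)
    dim(dz) <- d
    list(dz)
  })
}
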