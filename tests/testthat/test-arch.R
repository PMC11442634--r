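# Architecture: shape contracts, parameter budgets, structural properties.

test_that("patch embedding reduces spatial dims by 4 and matches its budget", {
  pe <- pnl$layer_patch_embed(3L, 96L)
  x <- pnl$ag_tensor(array(rnorm(64 * 64 * 3), c(64, 64, 3, 1)))
  y <- pnl$module_forward(pe, x)
  expect_equal(dim(y$value), c(16, 16, 96, 1))
  x2 <- pnl$ag_tensor(array(rnorm(256 * 256 * 3), c(256, 256, 3, 1)))
  expect_equal(dim(pnl$module_forward(pe, x2)$value), c(64, 64, 96, 1))
  expect_equal(count_parameters(pe), cf_patch_embed())
  expect_equal(cf_patch_embed(), 4896)
  x3 <- pnl$ag_tensor(array(rnorm(30 * 64 * 3), c(30, 64, 3, 1)))
  expect_error(pnl$module_forward(pe, x3), "height 30")
})

test_that("ConvNext block preserves shape, matches its budget, and is the
           identity with zeroed weights", {
  blk <- pnl$layer_convnext_block(96)
  expect_equal(count_parameters(blk), cf_convnext_block(96))
  expect_equal(cf_convnext_block(96), 79296)
  x <- pnl$ag_tensor(array(rnorm(12 * 12 * 96), c(12, 12, 96, 1)))
  y <- pnl$module_forward(blk, x)
  expect_equal(dim(y$value), dim(x$value))
  for (p in pnl$collect_parameters(blk)) p$value <- p$value * 0
  y0 <- pnl$module_forward(blk, x)
  expect_identical(y0$value, x$value)
  xb <- pnl$ag_tensor(array(rnorm(12 * 12 * 64), c(12, 12, 64, 1)))
  expect_error(pnl$module_forward(blk, xb), "64 channels")
})

test_that("backbone parameter counts match the closed-form sums and the
           published millions", {
  cfg <- model_config(seed = 0L)
  reduced <- build_reduced_backbone(cfg)
  unpruned <- build_unpruned_backbone(cfg)
  expect_equal(count_parameters(reduced), cf_reduced_backbone())
  expect_equal(count_parameters(unpruned), cf_unpruned_backbone())
  expect_equal(pnl$round_half_up(count_parameters(reduced) / 1e6), 12.35)
  expect_equal(pnl$round_half_up(count_parameters(unpruned) / 1e6), 27.82)
  # pruning removes the fourth stage: ~15.47M parameters
  expect_equal(round((count_parameters(unpruned) -
                        count_parameters(reduced)) / 1e6, 2), 15.47)
})

test_that("encoder pyramid and unpruned final map have the stated scales", {
  cfg <- model_config(seed = 0L)
  enc <- build_unpruned_backbone(cfg)
  x <- pnl$ag_tensor(array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2)))
  pyr <- pnl$encoder_forward(enc, x)
  expect_equal(dim(pyr$skip4$value), c(16, 16, 96, 2))
  expect_equal(dim(pyr$skip8$value), c(8, 8, 192, 2))
  expect_equal(dim(pyr$bottleneck$value), c(4, 4, 384, 2))
  expect_equal(dim(pyr$final$value), c(2, 2, 768, 2))
})

test_that("fusion and decoder match their closed-form parameter budgets", {
  cfg <- model_config(seed = 0L)
  expect_equal(count_parameters(build_biconvlstm(cfg)), cf_biconvlstm())
  expect_equal(cf_biconvlstm(), 7964160)
  dec <- build_decoder(cfg)
  expect_equal(count_parameters(dec), cf_decoder())
  expect_equal(count_parameters(pnl$layer_double_conv(384L, 192L)), 996480)
  expect_equal(round(cf_decoder() / 1e6, 2), 1.64)
  # conservation: full model = encoder + fusion + decoder
  expect_equal(count_parameters(build_polypnextlstm(cfg)),
               cf_reduced_backbone() + cf_biconvlstm() + cf_decoder())
})

test_that("bidirectional ConvLSTM honours its shape contract and
           frame-reversal symmetry", {
  fus <- build_biconvlstm(model_config(seed = 2))
  set.seed(7)
  x <- array(rnorm(1 * 5 * 384 * 4 * 4), c(1, 5, 384, 4, 4))
  y <- biconvlstm_apply(fus, x)
  expect_equal(dim(y), c(1, 5, 384, 4, 4))
  # with the two cells' weights tied, reversing the input frames gives the
  # frame-reversed output with its 192-channel halves swapped, exactly
  pf <- pnl$collect_parameters(fus$children$fwd)
  pb <- pnl$collect_parameters(fus$children$bwd)
  for (nm in names(pf)) pb[[nm]]$value <- pf[[nm]]$value
  yf <- biconvlstm_apply(fus, x)
  yr <- biconvlstm_apply(fus, x[, 5:1, , , , drop = FALSE])
  swapped <- yr[, 5:1, c(193:384, 1:192), , , drop = FALSE]
  expect_identical(yf, swapped)
  xb <- pnl$ag_tensor(array(rnorm(4 * 4 * 100 * 5), c(4, 4, 100, 5)))
  expect_error(pnl$biconvlstm_forward_internal(fus, xb, 1L, 5L),
               "expected 384 channels")
})

test_that("encoder features permute with the frames (independence before
           fusion)", {
  cfg <- model_config(seed = 6)
  enc <- build_reduced_backbone(cfg)
  set.seed(8)
  x <- array(runif(48 * 48 * 3 * 3), c(48, 48, 3, 3))
  perm <- c(3, 1, 2)
  p1 <- pnl$encoder_forward(enc, pnl$ag_tensor(x))
  p2 <- pnl$encoder_forward(enc, pnl$ag_tensor(x[, , , perm]))
  expect_identical(p1$bottleneck$value[, , , perm], p2$bottleneck$value)
  expect_identical(p1$skip4$value[, , , perm], p2$skip4$value)
})

test_that("the full model maps B x F x 3 x H x W to one logit map per frame", {
  m <- build_polypnextlstm(model_config(seed = 1))
  set.seed(1)
  clip <- array(runif(2 * 3 * 3 * 64 * 64), c(2, 3, 3, 64, 64))
  y <- model_forward(m, clip)
  expect_equal(dim(y), c(2, 3, 1, 64, 64))
  # degenerate single-frame clip is valid
  y1 <- model_forward(m, clip[1, 1, , , , drop = FALSE])
  expect_equal(dim(y1), c(1, 1, 1, 64, 64))
  expect_error(model_forward(m, array(0, c(1, 2, 3, 60, 64))),
               "divisible by 16")
  expect_error(model_forward(m, array(0, c(1, 2, 1, 64, 64))),
               "3 channels")
})

test_that("checkpoints round-trip weights and reproduce predictions", {
  m <- build_polypnextlstm(model_config(seed = 12))
  set.seed(2)
  clip <- array(runif(1 * 2 * 3 * 32 * 32), c(1, 2, 3, 32, 32))
  y1 <- model_forward(m, clip)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- model_from_checkpoint(ck)
  expect_identical(model_forward(m2, clip), y1)
  expect_equal(count_parameters(m2), count_parameters(m))
})

test_that("parameter summary reports per-submodule counts that sum correctly", {
  cfg <- model_config(seed = 0L)
  m <- build_polypnextlstm(cfg)
  s <- parameter_summary(m)
  expect_equal(s$n_params[s$module == "model"], count_parameters(m))
  expect_equal(s$n_params[s$module == "model/fusion"], cf_biconvlstm())
  empty <- pnl$pnl_module("stage")
  expect_equal(count_parameters(empty), 0L)
})
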