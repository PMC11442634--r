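# Overlap metrics, boundary distance, loss, attribute aggregation.

test_that("dice score matches hand examples and conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(dice_score(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice_score(a, b), 0)
  # |P| = 4, |G| = 2, overlap 2 -> 2*2/6
  g <- matrix(FALSE, 4, 4); g[1:2, 1] <- TRUE
  expect_equal(dice_score(a, g), 2 * 2 / 6)
  expect_equal(dice_score(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_error(dice_score(a, matrix(FALSE, 3, 3)), "dims differ")
})

test_that("iou matches hand examples and the dice identity holds on random masks", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  g <- matrix(FALSE, 4, 4); g[1:2, 1] <- TRUE
  expect_equal(iou_score(a, a), 1)
  expect_equal(iou_score(a, g), 0.5)
  set.seed(42)
  for (i in 1:200) {
    p <- matrix(runif(15 * 15) < runif(1, 0.1, 0.6), 15, 15)
    q <- matrix(runif(15 * 15) < runif(1, 0.1, 0.6), 15, 15)
    d <- dice_score(p, q); j <- iou_score(p, q)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("recall matches hand examples and the empty-gt convention", {
  gt <- matrix(FALSE, 4, 4); gt[1:2, 1:2] <- TRUE
  all_on <- matrix(TRUE, 4, 4)
  expect_equal(recall_score(all_on, gt), 1)
  expect_equal(recall_score(matrix(FALSE, 4, 4), gt), 0)
  # TP = 3, FN = 1
  pr <- gt; pr[2, 2] <- FALSE
  expect_equal(recall_score(pr, gt), 0.75)
  expect_equal(recall_score(pr, matrix(FALSE, 4, 4)), 1)
})

test_that("hd95 reproduces hand-computed cases", {
  a <- matrix(FALSE, 8, 8); a[1, 1] <- TRUE
  expect_equal(hd95(a, a), 0)
  b <- matrix(FALSE, 8, 8); b[4, 5] <- TRUE  # offset (3, 4) -> distance 5
  expect_equal(hd95(a, b), 5)
  # boundaries {(1,1), (1,11)} vs {(1,1)}: perc95 of {0, 10} = 9.5
  p <- matrix(FALSE, 3, 12); p[1, 1] <- TRUE; p[1, 11] <- TRUE
  g <- matrix(FALSE, 3, 12); g[1, 1] <- TRUE
  expect_equal(hd95(p, g), 9.5)
})

test_that("hd95 equals the brute-force pairwise computation on small masks
           and is bounded by the full Hausdorff distance", {
  set.seed(99)
  for (i in 1:30) {
    p <- random_small_mask(); g <- random_small_mask()
    bp <- sum(pnl$mask_boundary(p)); bg <- sum(pnl$mask_boundary(g))
    expect_lte(max(bp, bg), 50)
    expect_equal(as.numeric(hd95(p, g)), bf_hd95(p, g), tolerance = 1e-12)
    expect_lte(as.numeric(hd95(p, g)), bf_hausdorff(p, g) + 1e-12)
  }
})

test_that("hd95 empty-mask conventions: 0 for both empty, flagged diagonal
           sentinel for one empty", {
  e <- matrix(FALSE, 6, 8)
  m <- matrix(FALSE, 6, 8); m[3, 3] <- TRUE
  expect_equal(hd95(e, e), 0)
  s <- hd95(m, e)
  expect_equal(as.numeric(s), sqrt(6^2 + 8^2))
  expect_true(isTRUE(attr(s, "sentinel")))
})

test_that("dice+bce loss matches its closed forms", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_bce_loss(t, t), 0)              # perfect prediction
  # probs all 0.5 against an all-ones target: bce term is ln 2, dice term
  # 1 - (2*2 + 1)/(2 + 4 + 1)
  p <- matrix(0.5, 2, 2); tt <- matrix(1, 2, 2)
  expect_equal(dice_bce_loss(p, tt),
               (1 - (2 * 2 + 1) / (2 + 4 + 1)) + log(2), tolerance = 1e-12)
  expect_error(dice_bce_loss(matrix(1.5, 2, 2), tt), "\\[0, 1\\]")
  # saturated all-ones prediction vs 2 positive pixels: the dice term is
  # 1 - (2*2+1)/(4+2+1) = 1 - 5/7; the stable-bce term is 60 on each of
  # the two zero-target pixels
  z <- array(60, c(2, 2, 1, 1))
  t2 <- array(c(1, 1, 0, 0), c(2, 2, 1, 1))
  expect_equal(pnl$ag_dice_bce_loss(pnl$ag_tensor(z), t2)$value,
               (1 - 5 / 7) + 30, tolerance = 1e-9)
})

test_that("the differentiable loss agrees with the reference loss and is
           zero only at the target", {
  set.seed(4)
  z <- array(rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  t <- array((runif(6 * 6 * 2) < 0.4) * 1, c(6, 6, 1, 2))
  lt <- pnl$ag_tensor(z)
  l1 <- pnl$ag_dice_bce_loss(lt, t)$value
  probs <- stats::plogis(z)
  dim(probs) <- dim(z)
  expect_equal(l1, dice_bce_loss(probs, t), tolerance = 1e-12)
  expect_gt(l1, 0)
  # at a hard 0/1 match the loss vanishes: push logits far toward the target
  zbig <- (t * 2 - 1) * 60
  expect_lt(pnl$ag_dice_bce_loss(pnl$ag_tensor(zbig), t)$value, 1e-10)
})

test_that("attribute-stratified aggregation averages clips per attribute", {
  scores <- c(clipA = 0.6, clipB = 0.8)
  attrs <- list(clipA = c("FM", "SO"), clipB = "FM")
  out <- aggregate_by_attribute(scores, attrs)
  expect_equal(out[["FM"]], 0.7)
  expect_equal(out[["SO"]], 0.6)
  expect_false("LO" %in% names(out))   # unrepresented attribute absent
  one <- aggregate_by_attribute(c(c1 = 0.8), list(c1 = "FM"))
  expect_equal(one[["FM"]], 0.8)
  expect_error(aggregate_by_attribute(scores, list(clipA = "XX", clipB = "FM")),
               "unknown attribute")
  expect_error(aggregate_by_attribute(c(zz = 1), attrs), "must appear")
})

test_that("metric reports print, aggregate and round-trip to CSV/JSON", {
  per_clip <- data.frame(clip_id = c("a", "b"), dice = c(0.9, 0.7),
                         iou = c(0.82, 0.54), hd95 = c(1.5, 3),
                         recall = c(0.95, 0.8))
  rep <- metric_report(per_clip, list(a = "FM", b = c("FM", "SO")))
  expect_equal(unname(rep$aggregate["dice"]), 0.8)
  expect_equal(rep$by_attribute[["FM"]], 0.8)
  expect_output(print(rep), "mean dice 0.8000")
  d <- tempfile()
  write_metric_report(rep, d)
  back <- read.csv(file.path(d, "metrics.csv"))
  expect_equal(back$dice, per_clip$dice)
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(js$aggregate$dice, 0.8)
})
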