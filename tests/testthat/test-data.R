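# Dataset scanning, filtering, windowing, loading, augmentation, folds.

make_tree <- function(n_clips = 2, n_frames = 12, size = c(32, 32)) {
  dir <- tempfile("tree")
  make_benchmark_suite(dir, n_clips = n_clips, seed = 3,
                       image_size = size, n_frames = n_frames)
  dir
}

test_that("scan_dataset reads clips, masks and attributes and validates pairing", {
  dir <- make_tree(2, 12)
  recs <- scan_dataset(dir)
  expect_length(recs, 2)
  expect_equal(vapply(recs, function(r) length(r$frame_paths), numeric(1)),
               c(12, 12))
  expect_equal(vapply(recs, function(r) length(r$mask_paths), numeric(1)),
               c(12, 12))
  # attribute parsing: semicolon-separated ids
  att <- read.csv(file.path(dir, "attributes.csv"))
  expected <- strsplit(att$attributes[att$clip_id == recs[[2]]$clip_id],
                       ";")[[1]]
  expect_setequal(recs[[2]]$attributes, expected)
  # removing one mask is a hard error naming the frame
  file.remove(recs[[1]]$mask_paths[3])
  expect_error(scan_dataset(dir), "missing mask.*frame_0003",
               ignore.case = TRUE)
})

test_that("first_clip_per_polyp keeps the lexicographically first clip per case", {
  rec <- function(id, case) structure(
    list(clip_id = id, polyp_case_id = case, frame_paths = "f",
         mask_paths = "m", attributes = character(0)),
    class = "clip_record")
  recs <- list(rec("a_2", "a"), rec("a_1", "a"), rec("b_1", "b"))
  kept <- first_clip_per_polyp(recs)
  expect_equal(vapply(kept, `[[`, "", "clip_id"), c("a_1", "b_1"))
  distinct <- list(rec("a_1", "a"), rec("b_1", "b"), rec("c_1", "c"))
  expect_length(first_clip_per_polyp(distinct), 3)
})

test_that("a 51-polyp tree with 1-3 clips each reduces to 51 records", {
  dir <- tempfile("poly51")
  make_benchmark_suite(dir, n_clips = 51, seed = 5,
                       image_size = c(32, 32), n_frames = 2,
                       clips_per_polyp = rep_len(1:3, 51))
  recs <- scan_dataset(dir)
  expect_gt(length(recs), 51)
  expect_length(first_clip_per_polyp(recs), 51)
})

test_that("windowing follows the end-anchored remainder rule", {
  rec <- structure(list(clip_id = "c", polyp_case_id = "c",
                        frame_paths = paste0("f", 1:12),
                        mask_paths = paste0("m", 1:12),
                        attributes = character(0)), class = "clip_record")
  starts <- vapply(make_windows(rec, 5), `[[`, 0L, "start")
  expect_equal(starts, c(0L, 5L, 7L))
  rec$frame_paths <- rec$mask_paths <- paste0("f", 1:10)
  expect_equal(vapply(make_windows(rec, 5), `[[`, 0L, "start"), c(0L, 5L))
  rec$frame_paths <- rec$mask_paths <- paste0("f", 1:5)
  expect_equal(vapply(make_windows(rec, 5), `[[`, 0L, "start"), 0L)
  rec$frame_paths <- rec$mask_paths <- paste0("f", 1:3)
  expect_warning(w <- make_windows(rec, 5), "skipped")
  expect_length(w, 0)
})

test_that("windows cover every frame of every clip at least F frames long", {
  rec0 <- structure(list(clip_id = "c", polyp_case_id = "c",
                         attributes = character(0)), class = "clip_record")
  for (L in 5:23) {
    rec <- rec0
    rec$frame_paths <- rec$mask_paths <- paste0("f", seq_len(L))
    wins <- make_windows(rec, 5)
    covered <- sort(unique(unlist(lapply(wins, function(w)
      w$start + seq_len(w$length)))))
    expect_equal(covered, seq_len(L), label = paste("coverage at L =", L))
    expect_true(all(vapply(wins, function(w)
      w$start + w$length <= L, logical(1))))
  }
})

test_that("load_window resizes frames bilinearly and keeps masks binary
           with roughly preserved area", {
  dir <- tempfile("odd")
  spec <- synth_clip_spec(n_frames = 5, image_size = c(96, 72),
                          velocity = c(0.5, 0.5), seed = 2)
  write_clip(render_clip(spec), file.path(dir, "case001_1"))
  recs <- scan_dataset(dir)
  w <- make_windows(recs[[1]], 5)[[1]]
  lw <- load_window(recs[[1]], w, size = c(64, 64))
  expect_equal(dim(lw$frames), c(64, 64, 3, 5))
  expect_equal(dim(lw$masks), c(64, 64, 1, 5))
  expect_true(all(lw$masks %in% c(0, 1)))
  orig <- render_clip(spec)$masks
  for (f in 1:5) {
    expect_lt(abs(mean(lw$masks[, , 1, f]) - mean(orig[, , f])), 0.02)
  }
  # imagenet normalization applies the fixed per-channel standardization
  lw2 <- load_window(recs[[1]], w, size = c(64, 64),
                     normalize = "imagenet")
  expect_equal(lw2$frames[, , 1, 1], (lw$frames[, , 1, 1] - 0.485) / 0.229,
               tolerance = 1e-12)
  expect_equal(lw2$frames[, , 3, 2], (lw$frames[, , 3, 2] - 0.406) / 0.225,
               tolerance = 1e-12)
})

test_that("augmentation draws once per window and applies it to all frames
           and masks alike", {
  spec <- synth_clip_spec(n_frames = 5, image_size = c(64, 64),
                          velocity = c(0, 0), seed = 4)
  clip <- render_clip(spec)
  frames <- clip$frames
  masks <- array(clip$masks * 1, c(64, 64, 1, 5))
  a1 <- augment_window(frames, masks, seed = 7)
  a2 <- augment_window(frames, masks, seed = 7)
  expect_identical(a1$frames, a2$frames)   # deterministic under seed
  expect_identical(a1$masks, a2$masks)
  # static input: every augmented frame must be identical (single draw)
  for (f in 2:5) {
    expect_identical(a1$frames[, , , f], a1$frames[, , , 1])
    expect_identical(a1$masks[, , , f], a1$masks[, , , 1])
  }
  # frame and mask receive the same geometric map: a painted disc
  # re-detected in the augmented frame stays aligned with the augmented
  # mask of that disc
  H <- 128
  y <- matrix(seq_len(H), H, H); x <- t(y)
  disc <- (y - 64)^2 + (x - 64)^2 <= 45^2
  dframes <- array(0.1, c(H, H, 3, 2))
  dmasks <- array(0, c(H, H, 1, 2))
  for (f in 1:2) {
    for (ch in 1:3) dframes[, , ch, f][disc] <- 1
    dmasks[, , 1, f] <- disc * 1
  }
  aug <- augment_window(dframes, dmasks, seed = 13)
  detected <- aug$frames[, , 1, 1] > 0.5
  m <- aug$masks[, , 1, 1] > 0.5
  expect_gte(sum(detected & m) / sum(detected | m), 0.95)
})

test_that("5-fold splits are a seed-deterministic partition at clip level", {
  dir <- make_tree(10, 6)
  recs <- scan_dataset(dir)
  f1 <- make_folds(recs, 5, seed = 3)
  f2 <- make_folds(recs, 5, seed = 3)
  expect_identical(f1, f2)
  vals <- lapply(f1, `[[`, "val")
  expect_true(all(lengths(vals) == 2))
  expect_setequal(unlist(vals), vapply(recs, `[[`, "", "clip_id"))
  expect_equal(sum(lengths(vals)), 10)     # disjoint: union size == total
  for (f in f1) expect_length(intersect(f$train, f$val), 0)
  expect_error(make_folds(recs[1:3], 5, seed = 1), "exceeds")
})
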