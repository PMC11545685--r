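# Quality filtering, normalization, clip splitting, patient splits.

test_that("quality filter flags the three defect classes in order", {
  black <- matrix(0, 64, 64)
  q <- assess_frame_quality(black)
  expect_false(q$keep)
  expect_equal(q$reason, "blackness")

  # sharp checkerboard passes, its blurred version fails, at a threshold
  # fixed between the two sharpness scores
  cb <- 255 * outer(1:64, 1:64, function(r, c) (r + c) %% 2)
  blurred <- round(wunet:::gaussian_blur(cb, 8))
  s_sharp <- laplacian_variance(cb)
  s_blur <- laplacian_variance(blurred)
  expect_gt(s_sharp, s_blur)
  thr <- quality_thresholds(blur_threshold = (s_sharp + s_blur) / 2)
  expect_true(assess_frame_quality(cb, thresholds = thr)$keep)
  qb <- assess_frame_quality(blurred, thresholds = thr)
  expect_false(qb$keep)
  expect_equal(qb$reason, "blurry")

  # an empty mask flags no_target even for a sharp frame
  qt <- assess_frame_quality(cb, mask = matrix(0, 64, 64), thresholds = thr)
  expect_equal(qt$reason, "no_target")
  # keep = TRUE iff reason == "ok"
  qo <- assess_frame_quality(cb, mask = matrix(1, 64, 64), thresholds = thr)
  expect_true(qo$keep && qo$reason == "ok")

  expect_error(assess_frame_quality(matrix(300, 4, 4)), "255")
  expect_error(assess_frame_quality("frame"), "matrix")
})

test_that("normalize_frame maps 8-bit to [0,1] at 256x256 and is idempotent", {
  expect_equal(normalize_frame(matrix(255, 64, 64)),
               matrix(1, 256, 256))
  expect_equal(normalize_frame(matrix(0, 64, 64)), matrix(0, 256, 256))
  big <- matrix(runif(512 * 512, 0, 255), 512, 512)
  out <- normalize_frame(big)
  expect_equal(dim(out), c(256L, 256L))
  expect_true(min(out) >= 0 && max(out) <= 1)
  # already-normalized input passes through unchanged
  expect_equal(normalize_frame(out), out, tolerance = 1e-6)
  expect_error(normalize_frame(matrix(numeric(0), 0, 0)), "matrix")
})

test_that("mask normalization stays strictly binary under resize", {
  m <- matrix(0, 100, 100)
  m[30:60, 40:70] <- 1
  out <- normalize_mask(m, 256)
  expect_true(all(out %in% c(0, 1)))
  expect_equal(dim(out), c(256L, 256L))
  out255 <- normalize_mask(255 * m, 64)
  expect_true(all(out255 %in% c(0, 1)))
  expect_gt(sum(out255), 0)
})

test_that("clip splitting cuts on structural change and partitions frames", {
  same <- replicate(10, matrix(5, 8, 8), simplify = FALSE)
  r <- split_clip_on_structural_change(same, 0.001)
  expect_equal(r, data.frame(start = 1L, end = 10L))

  jump <- c(replicate(5, matrix(10, 8, 8), simplify = FALSE),
            replicate(5, matrix(200, 8, 8), simplify = FALSE))
  r2 <- split_clip_on_structural_change(jump, 50)
  expect_equal(r2, data.frame(start = c(1L, 6L), end = c(5L, 10L)))

  expect_equal(split_clip_on_structural_change(same[1], 1),
               data.frame(start = 1L, end = 1L))

  # property: ranges always partition the frame run exactly
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    frames <- lapply(seq_len(n), function(j) matrix(runif(16, 0, 255), 4, 4))
    rr <- split_clip_on_structural_change(frames, runif(1, 0, 120))
    expect_equal(rr$start[1], 1L)
    expect_equal(rr$end[nrow(rr)], n)
    if (nrow(rr) > 1) {
      expect_equal(rr$start[-1], rr$end[-nrow(rr)] + 1L)
    }
  }
})

test_that("patient split has the right sizes and is deterministic", {
  ids22 <- sprintf("P%02d", 1:22)
  s <- make_patient_split(ids22, seed = 4)
  sizes <- lengths(s[c("train", "val", "test")])
  expect_equal(sum(sizes), 22L)
  expect_equal(unname(sizes), c(13L, 2L, 7L))
  expect_identical(make_patient_split(ids22, seed = 4), s)
  expect_false(identical(make_patient_split(ids22, seed = 5), s))

  s3 <- make_patient_split(c("a", "b", "c"), seed = 1)
  expect_equal(unname(lengths(s3[c("train", "val", "test")])),
               c(1L, 1L, 1L))
  expect_error(make_patient_split(c("a", "b"), seed = 1), "3 distinct")
})

test_that("no patient ever lands in two partitions", {
  ids <- sprintf("P%02d", 1:17)
  for (seed in 1:200) {
    s <- make_patient_split(ids, seed = seed)
    expect_length(intersect(s$train, s$val), 0)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$val, s$test), 0)
    expect_setequal(c(s$train, s$val, s$test), ids)
  }
})

test_that("split manifest round-trips through JSON", {
  s <- make_patient_split(sprintf("P%d", 1:8), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(s, path)
  expect_equal(read_split_manifest(path), s)
})

test_that("quality report covers every frame with statistics", {
  clip <- generate_clip(phantom_preset("hard", image_side = 64,
                                       frames_per_clip = 8, seed = 2),
                        patient_id = "P01")
  rep <- quality_report(list(clip))
  expect_equal(nrow(rep), 8)
  expect_equal(rep$frame_index, 0:7)
  expect_true(all(c("keep", "reason", "dark_fraction", "sharpness") %in%
                    names(rep)))
})
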