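# The weighted attention U-Net: kernels, block algebra, shape contracts.

test_that("3x3 convolution kernel matches a direct triple-loop oracle", {
  set.seed(14)
  H <- 7; W <- 6; cin <- 3; cout <- 2
  x <- array(runif(H * W * cin), c(H, W, cin))
  Wm <- matrix(runif(cout * cin * 9, -1, 1), cout, cin * 9)
  b <- runif(cout)
  got <- wunet:::cpp_conv3x3(x, Wm, b)

  ref <- array(0, c(H, W, cout))
  for (co in 1:cout) for (r in 1:H) for (c in 1:W) {
    acc <- b[co]
    for (ci in 1:cin) for (dc in -1:1) for (dr in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
        off <- (dc + 1) * 3 + (dr + 1)
        acc <- acc + Wm[co, (ci - 1) * 9 + off + 1] * x[rr, cc, ci]
      }
    }
    ref[r, c, co] <- acc
  }
  expect_equal(got, ref, tolerance = 1e-5)
})

test_that("weighted block obeys its gating algebra", {
  set.seed(2)
  lfm <- array(runif(32 * 32 * 4), c(32, 32, 4))
  w <- matrix(runif(32 * 32), 32, 32)           # full-size map: pooled inside
  blk <- weighted_block(lfm, w, attention_channels = 6, seed = 5)
  expect_equal(dim(blk$O), c(16L, 16L, 6L))
  expect_equal(dim(blk$X), c(16L, 16L))
  expect_true(all(blk$X >= 0 & blk$X <= 1))
  # O = X * Q element-wise with X broadcast across channels
  expect_equal(blk$O, sweep(blk$Q, c(1, 2), blk$X, `*`), tolerance = 1e-6)
  # monotone gating: scaling X by 0.5 scales O by exactly 0.5
  expect_identical(sweep(blk$Q, c(1, 2), 0.5 * blk$X, `*`),
                   0.5 * sweep(blk$Q, c(1, 2), blk$X, `*`))
  # a half-size map is accepted as the pyramid level directly
  blk2 <- weighted_block(lfm, blk$X * 0, attention_channels = 6, seed = 5)
  expect_equal(dim(blk2$X), c(16L, 16L))
})

test_that("zero features and zero map give X = sigmoid(0) = 0.5, O = 0", {
  a <- 4
  zeros <- function(cin, cout, k) list(W = matrix(0, cout, cin * k * k),
                                       b = rep(0, cout))
  wts <- list(proj = zeros(2, a, 1), lift = zeros(1, a, 1),
              ref = zeros(a, a, 3), gate = zeros(a, 1, 1))
  blk <- weighted_block(array(0, c(16, 16, 2)), matrix(0, 8, 8),
                        weights = wts)
  expect_equal(blk$X, matrix(0.5, 8, 8))
  expect_equal(blk$O, array(0, c(8, 8, a)))
})

test_that("forward pass keeps shape and range contracts", {
  cfg <- tiny_mconfig(64)
  m <- build_model(cfg, seed = 2)
  set.seed(6)
  x <- matrix(runif(64 * 64), 64, 64)
  w <- matrix(runif(64 * 64), 64, 64)
  p <- predict_prob(m, x, w)
  expect_equal(dim(p), c(64L, 64L, 1L))
  expect_true(all(p >= 0 & p <= 1))

  dbg <- wunet:::cpp_net_forward_debug(m$ptr, array(x, c(64, 64, 1)),
                                       array(w, c(64, 64, 1)))
  for (l in 1:4) {
    expect_equal(dbg$skip_dims[[l]],
                 c(64L %/% 2L^l, 64L %/% 2L^l, cfg$attention_channels))
    g <- dbg$gates[[l]]
    expect_true(all(g >= 0 & g <= 1))
  }
})

test_that("batched forward equals per-item forward and is deterministic", {
  m <- build_model(tiny_mconfig(32), seed = 4)
  set.seed(8)
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  w <- array(runif(32 * 32 * 4), c(32, 32, 4))
  pb <- predict_prob(m, x, w)
  for (i in 1:4) {
    expect_identical(pb[, , i], predict_prob(m, x[, , i], w[, , i])[, , 1])
  }
  expect_identical(predict_prob(m, x, w), pb)
})

test_that("parameter count equals the hand-tabulated layer sum", {
  # independent tabulation of (cin, cout, k) per layer for the default
  # architecture: encoder (32,32,64,64,128), attention width 128, decoder
  # (64,64,32,32), head 32; params per conv = (k^2 * cin + 1) * cout
  layers <- rbind(
    c(1, 32, 3), c(32, 32, 3), c(32, 64, 3), c(64, 64, 3), c(64, 128, 3),
    # weighted blocks l = 1..4: project z_l -> 128, lift 1 -> 128,
    # refine 128 -> 128 (3x3), gate 128 -> 1
    c(32, 128, 1), c(1, 128, 1), c(128, 128, 3), c(128, 1, 1),
    c(32, 128, 1), c(1, 128, 1), c(128, 128, 3), c(128, 1, 1),
    c(64, 128, 1), c(1, 128, 1), c(128, 128, 3), c(128, 1, 1),
    c(64, 128, 1), c(1, 128, 1), c(128, 128, 3), c(128, 1, 1),
    # decoder stages 4..1 on concat(prev, O_l)
    c(128 + 128, 64, 3), c(64, 64, 3),
    c(64 + 128, 64, 3), c(64, 64, 3),
    c(64 + 128, 32, 3), c(32, 32, 3),
    c(32 + 128, 32, 3), c(32, 32, 3),
    # head
    c(32, 32, 3), c(32, 1, 1))
  expected <- sum((layers[, 3]^2 * layers[, 1] + 1) * layers[, 2])
  m <- build_model(model_config(), seed = 1)
  expect_equal(n_parameters(m), expected)
})

test_that("predict thresholds behave at the extremes and need weight maps", {
  m <- build_model(tiny_mconfig(32), seed = 9)
  x <- matrix(runif(32 * 32), 32, 32)
  w <- matrix(runif(32 * 32), 32, 32)
  expect_true(all(predict(m, x, w, threshold = 0)$mask == 1))
  expect_true(all(predict(m, x, w, threshold = 1 + 1e-9)$mask == 0))
  expect_identical(predict(m, x, w)$prob, predict(m, x, w)$prob)
  expect_error(predict(m, x), "map")
  expect_error(predict_prob(m, x, matrix(0.5, 16, 16)), "match")
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_mconfig(32), seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- matrix(runif(32 * 32), 32, 32)
  w <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict_prob(m, x, w), predict_prob(m2, x, w))
  expect_equal(m2$config, m$config)
})

test_that("invalid model configurations are rejected", {
  expect_error(model_config(encoder_filters = c(32, 32)), "length 5")
  expect_error(model_config(kernel_size = 5), "kernel")
  expect_error(model_config(dropout_rate = 0.5), "dropout")
  expect_error(model_config(input_side = 100), "multiple of 16")
  expect_error(model_config(output_channels = 2), "single-channel")
})
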