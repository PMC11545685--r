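# Loss function and the per-vessel training loop.

test_that("losses match hand-computed values and stay non-negative", {
  m <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(compute_loss(m, m, "dice"), 0, tolerance = 1e-6)
  # prob = 0.5 everywhere, 2 of 4 pixels on: dice = 1 - (2+eps)/(4+eps)
  p <- matrix(0.5, 2, 2)
  expect_equal(compute_loss(p, m, "dice"),
               1 - (2 * 1 + 1e-6) / (2 + 2 + 1e-6))
  expect_equal(compute_loss(p, m, "dice"), 0.5, tolerance = 1e-6)
  # bce of a constant 0.5 prediction is log(2)
  expect_equal(compute_loss(p, m, "bce"), log(2))
  expect_equal(compute_loss(p, m, "bce_dice"),
               compute_loss(p, m, "bce") + compute_loss(p, m, "dice"))
  set.seed(10)
  for (i in 1:200) {
    pr <- matrix(runif(16), 4, 4)
    mk <- matrix(rbinom(16, 1, 0.5), 4, 4)
    for (kind in c("dice", "bce", "bce_dice")) {
      expect_gte(compute_loss(pr, mk, kind), 0)
    }
  }
  expect_error(compute_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "grid")
})

test_that("training configuration enforces the recipe constraints", {
  tc <- train_config()
  expect_equal(tc$learning_rate, 0.001)
  expect_equal(tc$batch_size, 16L)
  expect_equal(tc$epochs, 100L)
  expect_equal(tc$augmentation, "none")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(augmentation = "flips"), "augmentation")
  expect_error(train_config(optimizer = "sgd"), "adam")
})

make_tiny_training <- function() {
  cache_get("tiny_training", function() {
    clips <- make_corpus(4, clips_per_patient = 1, frames_per_clip = 8,
                         side = 64, seed = 17)
    split <- make_patient_split(sprintf("P%02d", 1:4), seed = 3)
    list(clips = clips, split = split)
  })
}

test_that("loss decreases over the first epochs on separable data", {
  inp <- make_tiny_training()
  fit <- train_vessel_model(inp$clips, inp$split, tiny_mconfig(64),
                            train_config(epochs = 5, seed = 21))
  h <- fit$history
  expect_equal(nrow(h), 5)
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_true(all(is.finite(h$val_dice)))
  expect_gte(fit$best_epoch, 1)
})

test_that("training is deterministic given the seed", {
  inp <- make_tiny_training()
  f1 <- train_vessel_model(inp$clips, inp$split, tiny_mconfig(64),
                           train_config(epochs = 2, seed = 33))
  f2 <- train_vessel_model(inp$clips, inp$split, tiny_mconfig(64),
                           train_config(epochs = 2, seed = 33))
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_dice, f2$history$val_dice)
  expect_identical(wunet:::model_weights(f1$model)$head_b,
                   wunet:::model_weights(f2$model)$head_b)
})

test_that("patient isolation and label purity are enforced", {
  inp <- make_tiny_training()
  bad_split <- structure(list(train = c("P01", "P02"), val = "P03",
                              test = c("P02", "P04")),
                         class = "wunet_split")
  expect_error(train_vessel_model(inp$clips, bad_split, tiny_mconfig(64),
                                  train_config(epochs = 1)),
               "disjoint")
  mixed <- inp$clips
  mixed[[1]]$vessel_label <- "RHV"
  expect_error(train_vessel_model(mixed, inp$split, tiny_mconfig(64),
                                  train_config(epochs = 1)),
               "mix vessel labels")
  empty_split <- structure(list(train = character(), val = "P01",
                                test = c("P02", "P03", "P04")),
                           class = "wunet_split")
  expect_error(train_vessel_model(inp$clips, empty_split, tiny_mconfig(64),
                                  train_config(epochs = 1)),
               "no frames")
})
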