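# Pixel-wise metrics against hand-enumerated and brute-force oracles.

# Brute-force oracle: walk every pixel and count.
oracle_counts <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

test_that("confusion counts match hand enumeration on a 3x3 grid", {
  truth <- matrix(0, 3, 3)
  truth[1:2, 1:2] <- 1                      # ones at (0,0),(0,1),(1,0),(1,1)
  pred <- matrix(0, 3, 3)
  pred[1, 1] <- pred[1, 2] <- pred[2, 1] <- pred[3, 3] <- 1
  cm <- confusion(pred, truth)
  expect_equal(cm$TP, 3)
  expect_equal(cm$FP, 1)
  expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 4)
  m <- metrics_from_counts(cm)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$accuracy, 7 / 9)
  expect_equal(m$iou, 0.6)
  expect_equal(m$dice, 0.75)
})

test_that("degenerate confusion inputs behave per the conventions", {
  ones <- matrix(1, 4, 4)
  zeros <- matrix(0, 4, 4)
  expect_equal(confusion(ones, ones)$TP, 16)
  expect_equal(confusion(ones, zeros)$FP, 16)
  # both empty: vacuous agreement
  m <- metrics_from_counts(confusion(zeros, zeros))
  expect_equal(unlist(m), c(dice = 1, iou = 1, recall = 1, precision = 1,
                            accuracy = 1))
  # truth empty, prediction not: recall undefined, overlap 0
  m2 <- metrics_from_counts(confusion(ones, zeros))
  expect_true(is.na(m2$recall))
  expect_equal(m2$dice, 0)
  expect_equal(m2$iou, 0)
  # perfect prediction
  m3 <- metrics_from_counts(confusion(ones, ones))
  expect_equal(m3$dice, 1)
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0, 2, 2)), "0,1")
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "grid")
})

test_that("count metrics agree with the brute-force oracle", {
  set.seed(11)
  for (i in 1:50) {
    pred <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    truth <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    cm <- confusion(pred, truth)
    oc <- oracle_counts(pred, truth)
    expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
                 oc[c("TP", "TN", "FP", "FN")])
    m <- metrics_from_counts(cm)
    # Dice and IoU satisfy their algebraic identity exactly
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-15)
  }
})

test_that("AUC matches the concordant-pair count and pROC", {
  truth <- c(1, 1, 1, 0, 0, 0)
  prob <- c(0.9, 0.8, 0.4, 0.6, 0.3, 0.2)
  expect_equal(auc_roc(prob, truth), 8 / 9)
  expect_equal(auc_roc(truth, truth), 1)          # prob = truth
  expect_equal(auc_roc(1 - truth, truth), 0)      # anti-predictor
  expect_warning(expect_true(is.na(auc_roc(prob, rep(1, 6)))), "single class")

  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:20) {
    y <- rbinom(60, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 60) next
    p <- round(runif(60), 2)                      # ties likely
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_roc(p, y), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(9)
  y <- rbinom(100, 1, 0.3)
  p <- runif(100)
  a0 <- auc_roc(p, y)
  expect_equal(auc_roc(qlogis(p * 0.98 + 0.01), y), a0)
  expect_equal(auc_roc(p^3, y), a0)
  expect_equal(auc_roc(100 * p - 3, y), a0)
})

test_that("aggregation reports mean and sample SD per vessel", {
  recs <- rbind(
    frame_metrics(matrix(c(1, 1, 0, 0), 2, 2), matrix(c(1, 0, 0, 0), 2, 2),
                  vessel = "IVC"),
    frame_metrics(matrix(c(1, 0, 0, 0), 2, 2), matrix(c(1, 0, 0, 0), 2, 2),
                  vessel = "IVC"),
    frame_metrics(matrix(c(1, 0, 0, 0), 2, 2), matrix(c(1, 0, 0, 0), 2, 2),
                  vessel = "RHV"))
  agg <- aggregate_metrics(recs)
  expect_equal(agg$vessel, c("IVC", "RHV"))
  # dice records for IVC: {2/3, 1} -> mean and n-1 SD
  expect_equal(agg$dice_mean[1], mean(c(2 / 3, 1)))
  expect_equal(agg$dice_sd[1], sd(c(2 / 3, 1)))
  # single record group: SD 0
  expect_equal(agg$dice_sd[2], 0)
  # reporting column order: Dice, IoU, Recall, Precision, Accuracy, AUC
  expect_equal(grep("_mean$", names(agg), value = TRUE),
               c("dice_mean", "iou_mean", "recall_mean", "precision_mean",
                 "accuracy_mean", "auc_mean"))
  # the {0.8, 1.0} example
  expect_equal(mean(c(0.8, 1)), 0.9)
  expect_equal(sd(c(0.8, 1)), 0.1414, tolerance = 1e-3)
})
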