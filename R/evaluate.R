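# Pixel-wise confusion counting and the segmentation metric suite.

#' Pixel-wise confusion counts between two binary masks
#'
#' @param pred,truth strictly \{0,1\}-valued matrices on the same grid.
#' @return object of class `wunet_confusion`: list with integer `TP`, `TN`,
#'   `FP`, `FN` summing to the number of pixels.
#' @export
confusion <- function(pred, truth) {
  check_binary_mask(pred, "pred")
  check_binary_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must share a grid", call. = FALSE)
  }
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "wunet_confusion")
}

#' Segmentation metrics from confusion counts
#'
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' accuracy = (TP+TN)/total, IoU = TP/(TP+FN+FP),
#' Dice = 2TP/(2TP+FP+FN) (the set form 2|X∩Y|/(|X|+|Y|) in counts).
#'
#' Zero-denominator convention: when truth and prediction are both empty the
#' overlap metrics and recall/precision are vacuously 1; when only one is
#' empty the corresponding ratio with a 0/0 denominator is reported `NA`
#' while Dice/IoU follow from the counts (0).
#'
#' @param counts a [confusion()] object (or a list with TP, TN, FP, FN).
#' @return list with dice, iou, recall, precision, accuracy.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts$TP
  tn <- counts$TN
  fp <- counts$FP
  fn <- counts$FN
  total <- tp + tn + fp + fn
  if (tp + fp + fn == 0) {                 # both masks empty
    return(list(dice = 1, iou = 1, recall = 1, precision = 1,
                accuracy = 1))
  }
  list(
    dice = 2 * tp / (2 * tp + fp + fn),
    iou = tp / (tp + fn + fp),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    accuracy = (tp + tn) / total
  )
}

#' Pixel-wise AUC-ROC of a probability map
#'
#' Rank-based (Mann-Whitney) area under the ROC curve over pixels, with
#' midranks for ties; invariant under strictly monotone transforms of the
#' probabilities.
#'
#' @param prob numeric probability matrix/vector.
#' @param truth \{0,1\} matrix/vector of the same length.
#' @return AUC in \[0, 1\], or `NA` (with a warning) when the truth contains
#'   a single class.
#' @export
auc_roc <- function(prob, truth) {
  p <- as.vector(prob)
  y <- as.vector(truth)
  if (length(p) != length(y)) stop("prob and truth must match", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("truth must be binary", call. = FALSE)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: truth contains a single class")
    return(NA_real_)
  }
  r <- rank(p)                             # midranks for ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full per-frame metrics record
#'
#' @param prob probability matrix.
#' @param truth \{0,1\} mask.
#' @param threshold probability cutoff for the binary metrics.
#' @param frame_id,vessel optional identifiers carried into the record.
#' @return one-row data.frame: dice, iou, recall, precision, accuracy, auc.
#' @export
frame_metrics <- function(prob, truth, threshold = 0.5, frame_id = NA,
                          vessel = NA) {
  cm <- confusion((prob >= threshold) * 1, truth)
  m <- metrics_from_counts(cm)
  auc <- if (sum(truth) > 0 && sum(truth) < length(truth)) {
    auc_roc(prob, truth)
  } else {
    NA_real_
  }
  data.frame(frame_id = frame_id, vessel = vessel, dice = m$dice,
             iou = m$iou, recall = m$recall, precision = m$precision,
             accuracy = m$accuracy, auc = auc, stringsAsFactors = FALSE)
}

#' Aggregate per-frame metrics as mean +/- SD per vessel
#'
#' Unweighted mean and sample standard deviation (n - 1) over frames; a
#' single-frame group reports SD 0.  Column order follows the reporting
#' convention: Dice, IoU, Recall, Precision, Accuracy, AUC-ROC.
#'
#' @param records data.frame of per-frame records (see [frame_metrics()]).
#' @param by grouping column, default `"vessel"`.
#' @return data.frame with one row per group: `<metric>_mean`,
#'   `<metric>_sd` for the six metrics, plus `n_frames`.
#' @export
aggregate_metrics <- function(records, by = "vessel") {
  metrics <- c("dice", "iou", "recall", "precision", "accuracy", "auc")
  groups <- split(records, records[[by]])
  groups <- Filter(function(g) nrow(g) > 0, groups)
  if (!length(groups)) {
    warning("no records to aggregate")
    return(data.frame())
  }
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    out <- data.frame(vessel = g, n_frames = nrow(df),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- df[[m]][!is.na(df[[m]])]
      out[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(m, "_sd")]] <- if (length(v) > 1) stats::sd(v) else 0
    }
    out
  })
  res <- do.call(rbind, rows)
  names(res)[names(res) == "vessel"] <- by
  res
}

#' Evaluate directories of predicted and true masks
#'
#' Pairs files by name across `pred_dir` and `truth_dir` (and optionally
#' `prob_dir` for AUC), computes per-frame metrics and writes the per-vessel
#' aggregate to `out_csv` when given.
#'
#' @param pred_dir,truth_dir directories of binary mask PNGs.
#' @param prob_dir optional directory of probability-map PNGs.
#' @param vessel vessel label stamped on the records.
#' @param out_csv optional output CSV path for the aggregate table.
#' @return list with `frames` (per-frame records) and `aggregate`.
#' @export
evaluate_mask_dirs <- function(pred_dir, truth_dir, prob_dir = NULL,
                               vessel = "vessel", out_csv = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "\\.png$"))
  if (!length(preds)) stop("no predicted masks in ", pred_dir, call. = FALSE)
  recs <- lapply(preds, function(f) {
    pred <- read_mask_image(file.path(pred_dir, f))
    truth <- read_mask_image(file.path(truth_dir, f))
    prob <- if (!is.null(prob_dir) && file.exists(file.path(prob_dir, f))) {
      read_frame_image(file.path(prob_dir, f)) / 255
    } else {
      pred
    }
    frame_metrics(prob, truth, frame_id = f, vessel = vessel)
  })
  frames <- do.call(rbind, recs)
  agg <- aggregate_metrics(frames)
  if (!is.null(out_csv)) write.csv(agg, out_csv, row.names = FALSE)
  list(frames = frames, aggregate = agg)
}
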