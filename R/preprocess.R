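# Frame quality filtering, normalization, clip splitting and patient splits.

#' Quality-filter thresholds
#'
#' Thresholds for the three degenerate-frame classes seen in IOUS video:
#' near-black frames (probe lifted off the organ), frames without the target
#' vessel, and motion-blurred frames.
#'
#' @param dark_value 8-bit intensity below which a pixel counts as dark.
#' @param dark_fraction flag a frame as black when at least this fraction of
#'   pixels is dark.  The default tolerates a few bright artifact pixels.
#' @param blur_threshold minimum variance of the 3x3 Laplacian response
#'   (8-bit intensity units squared) for a frame to count as sharp.  The
#'   default was calibrated on speckle phantoms, whose Laplacian variance is
#'   orders of magnitude above that of heavily blurred frames.
#' @return an object of class `wunet_quality_thresholds`.
#' @export
quality_thresholds <- function(dark_value = 10, dark_fraction = 0.95,
                               blur_threshold = 100) {
  structure(list(dark_value = dark_value, dark_fraction = dark_fraction,
                 blur_threshold = blur_threshold),
            class = "wunet_quality_thresholds")
}

#' Variance of the 3x3 Laplacian response
#'
#' Standard cheap focus measure: blur suppresses high spatial frequencies,
#' so the variance of the Laplacian response collapses for defocused or
#' motion-blurred frames.
#'
#' @param frame numeric matrix (8-bit scale).
#' @return scalar variance of the Laplacian response.
#' @export
laplacian_variance <- function(frame) {
  stopifnot_matrix(frame)
  h <- nrow(frame)
  w <- ncol(frame)
  if (h < 3 || w < 3) return(0)
  x <- frame
  lap <- 4 * x[2:(h - 1), 2:(w - 1)] -
    x[1:(h - 2), 2:(w - 1)] - x[3:h, 2:(w - 1)] -
    x[2:(h - 1), 1:(w - 2)] - x[2:(h - 1), 3:w]
  stats::var(as.vector(lap))
}

#' Assess the quality of one raw frame
#'
#' Flags the three defect classes in fixed priority order: `blackness`
#' (fraction of dark pixels above threshold), `no_target` (a mask is supplied
#' and has no foreground), then `blurry` (Laplacian variance below
#' threshold); otherwise `ok`.
#'
#' @param frame 8-bit frame matrix.
#' @param mask optional \{0,1\} mask; `NULL` when no annotation exists.
#' @param thresholds a [quality_thresholds()] object.
#' @return list with elements `keep` (logical), `reason`
#'   (`ok`/`blackness`/`no_target`/`blurry`) and `stats` (named numeric:
#'   dark fraction, sharpness).
#' @export
assess_frame_quality <- function(frame, mask = NULL,
                                 thresholds = quality_thresholds()) {
  check_raw_frame(frame)
  dark <- mean(frame < thresholds$dark_value)
  sharp <- laplacian_variance(frame)
  reason <- "ok"
  if (dark >= thresholds$dark_fraction) {
    reason <- "blackness"
  } else if (!is.null(mask) && sum(mask) == 0) {
    reason <- "no_target"
  } else if (sharp < thresholds$blur_threshold) {
    reason <- "blurry"
  }
  list(keep = reason == "ok", reason = reason,
       stats = c(dark_fraction = dark, sharpness = sharp))
}

#' Normalize a raw frame for the network
#'
#' Bilinear resize to `side` x `side`, then rescale 8-bit intensities to
#' \[0, 1\].  Input already on the \[0, 1\] scale (max <= 1) is resized but
#' not rescaled, making the operation idempotent.
#'
#' @param frame numeric frame matrix (8-bit or already normalized).
#' @param side output side in pixels.
#' @return `side` x `side` matrix with values in \[0, 1\].
#' @export
normalize_frame <- function(frame, side = 256) {
  stopifnot_matrix(frame)
  x <- if (max(frame) > 1) frame / 255 else frame
  if (nrow(x) != side || ncol(x) != side) {
    x <- EBImage::imageData(EBImage::resize(EBImage::Image(x), w = side, h = side))
  }
  clamp01(x)
}

#' @rdname normalize_frame
#' @param mask \{0,1\} (or 0/255) mask matrix; resized with nearest-neighbor
#'   interpolation so the output stays strictly binary.
#' @export
normalize_mask <- function(mask, side = 256) {
  stopifnot_matrix(mask, "mask")
  m <- if (max(mask) > 1) (mask >= 128) * 1 else mask
  check_binary_mask(m)
  if (nrow(m) != side || ncol(m) != side) {
    m <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = side, h = side,
                                   filter = "none"))
  }
  (m >= 0.5) * 1
}

#' Split a frame run where the vasculature changes structurally
#'
#' Reproducible proxy for the manual cut decisions made during annotation:
#' a cut is placed wherever the mean absolute intensity difference between
#' consecutive frames exceeds `threshold`.
#'
#' @param frames list of frame matrices (common grid).
#' @param threshold mean-absolute-difference cut threshold (8-bit units).
#' @return data.frame with 1-based inclusive columns `start`, `end`; the
#'   ranges are contiguous, non-overlapping and cover all frames.
#' @export
split_clip_on_structural_change <- function(frames, threshold) {
  if (!length(frames)) stop("need at least one frame", call. = FALSE)
  n <- length(frames)
  if (n == 1) return(data.frame(start = 1L, end = 1L))
  d <- vapply(seq_len(n - 1), function(i) {
    mean(abs(frames[[i + 1]] - frames[[i]]))
  }, numeric(1))
  cuts <- which(d > threshold)        # cut between frame i and i+1
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Patient-level train/validation/test split
#'
#' Partitions patient ids (never frames or clips) so that no patient
#' contributes to more than one partition; every clip inherits its patient's
#' partition, which rules out patient-level leakage by construction.
#'
#' @param patient_ids character vector of distinct patient ids (>= 3).
#' @param fractions train/validation/test fractions, by default 60/10/30.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return object of class `wunet_split`: list with `train`, `val`, `test`
#'   character vectors.
#' @export
make_patient_split <- function(patient_ids, fractions = c(0.6, 0.1, 0.3),
                               seed = 1) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (n < 3) stop("need at least 3 distinct patients", call. = FALSE)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three values summing to 1", call. = FALSE)
  }
  n_train <- max(1L, as.integer(round(fractions[1] * n)))
  n_val <- max(1L, as.integer(round(fractions[2] * n)))
  n_test <- n - n_train - n_val
  while (n_test < 1) {           # borrow from the largest partition
    if (n_train >= n_val && n_train > 1) n_train <- n_train - 1L
    else n_val <- n_val - 1L
    n_test <- n - n_train - n_val
  }
  perm <- with_seed(seed, sample(patient_ids))
  structure(
    list(train = sort(perm[seq_len(n_train)]),
         val = sort(perm[n_train + seq_len(n_val)]),
         test = sort(perm[n_train + n_val + seq_len(n_test)])),
    class = "wunet_split"
  )
}

#' @export
print.wunet_split <- function(x, ...) {
  cat(sprintf("<wunet_split> train %d / val %d / test %d patients\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Write or read a split manifest as JSON
#'
#' @param split a `wunet_split`.
#' @param path output JSON path.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(list(train = split$train, val = split$val,
                            test = split$test), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.character(x$train), val = as.character(x$val),
                 test = as.character(x$test)), class = "wunet_split")
}

#' Quality-filter every frame of a set of clips
#'
#' @param clips list of `wunet_clip` objects.
#' @param thresholds a [quality_thresholds()] object.
#' @return data.frame: clip_id, frame_index (0-based), keep, reason,
#'   dark_fraction, sharpness.
#' @export
quality_report <- function(clips, thresholds = quality_thresholds()) {
  rows <- lapply(clips, function(clip) {
    per <- lapply(seq_along(clip$frames), function(i) {
      q <- assess_frame_quality(clip$frames[[i]], clip$masks[[i]], thresholds)
      data.frame(clip_id = clip$clip_id, frame_index = i - 1L,
                 keep = q$keep, reason = q$reason,
                 dark_fraction = unname(q$stats["dark_fraction"]),
                 sharpness = unname(q$stats["sharpness"]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  do.call(rbind, rows)
}

# Drop frames flagged by the quality filter from a clip.
filter_clip <- function(clip, thresholds = quality_thresholds()) {
  keep <- vapply(seq_along(clip$frames), function(i) {
    assess_frame_quality(clip$frames[[i]], clip$masks[[i]], thresholds)$keep
  }, logical(1))
  clip$frames <- clip$frames[keep]
  clip$masks <- clip$masks[keep]
  if (!is.null(clip$wmaps)) clip$wmaps <- clip$wmaps[keep]
  if (!is.null(clip$labels)) clip$labels <- clip$labels[keep]
  clip
}
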