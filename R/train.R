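# Per-vessel training loop with strict patient-level isolation.

#' Training configuration
#'
#' Recipe defaults: Adam with learning rate 0.001, batch size 16,
#' 100 epochs, no data augmentation, frames treated as independent samples.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param loss `"dice"`, `"bce"` or `"bce_dice"` (sum of the two).
#' @param augmentation must be `"none"`; augmentation is excluded from the
#'   recipe by design.
#' @param optimizer only `"adam"` is supported.
#' @param beta1,beta2,adam_eps Adam moment decay and stabilizer constants.
#' @param seed seed controlling initialization and batch shuffling.
#' @return object of class `wunet_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16,
                         epochs = 100, loss = c("bce_dice", "dice", "bce"),
                         augmentation = "none", optimizer = "adam",
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = 1) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!identical(augmentation, "none")) {
    stop("augmentation must be \"none\"", call. = FALSE)
  }
  if (!identical(optimizer, "adam")) {
    stop("only the adam optimizer is supported", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 augmentation = "none", optimizer = "adam", beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed)),
            class = "wunet_train_config")
}

#' Segmentation loss
#'
#' Dice loss is `1 - (2*sum(p*m) + eps) / (sum(p) + sum(m) + eps)` with
#' `eps = 1e-6` for empty-mask stability; BCE is the standard pixel-mean
#' binary cross-entropy; `bce_dice` is their sum.
#'
#' @param prob probability matrix/array in \[0, 1\].
#' @param mask \{0,1\} matrix/array on the same grid.
#' @param kind loss kind.
#' @param eps Dice stabilizer.
#' @return non-negative scalar.
#' @export
compute_loss <- function(prob, mask, kind = c("bce_dice", "dice", "bce"),
                         eps = 1e-6) {
  kind <- match.arg(kind)
  if (!identical(dim(prob), dim(mask))) {
    stop("prob and mask must share a grid", call. = FALSE)
  }
  p <- as.vector(prob)
  m <- as.vector(mask)
  dice <- 1 - (2 * sum(p * m) + eps) / (sum(p) + sum(m) + eps)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -mean(m * log(pc) + (1 - m) * log(1 - pc))
  switch(kind, dice = dice, bce = bce, bce_dice = dice + bce)
}

# Stack the frames of selected clips into (H, W, N) arrays, normalizing
# frames/masks to the model side and picking the weight-map source.
assemble_arrays <- function(clips, patients, side,
                            wmap_source = c("ideal", "uniform", "estimate"),
                            sal_params = saliency_params(),
                            uniform_seed = 1) {
  wmap_source <- match.arg(wmap_source)
  keep <- Filter(function(cl) cl$patient_id %in% patients, clips)
  if (!length(keep)) {
    return(list(x = NULL, w = NULL, m = NULL, n = 0L,
                patients = character()))
  }
  xs <- list()
  ws <- list()
  ms <- list()
  for (cl in keep) {
    for (i in seq_along(cl$frames)) {
      x <- normalize_frame(cl$frames[[i]], side)
      m <- normalize_mask(cl$masks[[i]], side)
      w <- switch(wmap_source,
        ideal = {
          if (is.null(cl$wmaps)) {
            stop("clip ", cl$clip_id, " carries no weight maps",
                 call. = FALSE)
          }
          wm <- cl$wmaps[[i]]
          if (nrow(wm) != side) {
            wm <- clamp01(EBImage::imageData(EBImage::resize(EBImage::Image(wm),
                                                    w = side, h = side)))
          }
          wm
        },
        uniform = matrix(runif(side * side), side, side),
        estimate = estimate_weight_map(x, sal_params)
      )
      xs[[length(xs) + 1]] <- x
      ws[[length(ws) + 1]] <- w
      ms[[length(ms) + 1]] <- m
    }
  }
  n <- length(xs)
  list(x = array(unlist(xs), dim = c(side, side, n)),
       w = array(unlist(ws), dim = c(side, side, n)),
       m = array(unlist(ms), dim = c(side, side, n)),
       n = n, patients = unique(vapply(keep, `[[`, "", "patient_id")))
}

# Batched forward pass (keeps peak memory bounded for large frame sets).
predict_prob_batched <- function(model, x, w, batch = 16) {
  n <- dim(x)[3]
  out <- array(0, dim = dim(x))
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    out[, , s:e] <- predict_prob(model, x[, , s:e, drop = FALSE],
                                 w[, , s:e, drop = FALSE])
  }
  out
}

# Mean Dice/IoU/loss of a model over an (x, w, m) array set.
eval_arrays <- function(model, arr, loss_kind = "bce_dice",
                        threshold = 0.5) {
  prob <- predict_prob_batched(model, arr$x, arr$w)
  n <- dim(prob)[3]
  dice <- iou <- loss <- numeric(n)
  for (i in seq_len(n)) {
    m <- metrics_from_counts(confusion((prob[, , i] >= threshold) * 1,
                                       arr$m[, , i]))
    dice[i] <- m$dice
    iou[i] <- m$iou
    loss[i] <- compute_loss(prob[, , i], arr$m[, , i], loss_kind)
  }
  list(dice = mean(dice), iou = mean(iou), loss = mean(loss),
       per_frame_dice = dice)
}

#' Train the segmentation model for one vessel
#'
#' Trains on frames of training-partition patients only, validates each
#' epoch on the validation partition, and returns the epoch with the best
#' validation Dice.  Frames are treated as independent samples (shuffled
#' across clips each epoch).  Patient isolation is asserted before any
#' optimization: a patient id shared between train and test partitions is
#' an error.
#'
#' @param clips list of `wunet_clip` objects, all of ONE vessel label.
#' @param split a [make_patient_split()] result covering the clips'
#'   patients.
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param wmap_source which weight maps to train with: `"ideal"` (the
#'   clips' own maps, e.g. mask-derived for phantoms), `"uniform"`
#'   (uninformative random maps) or `"estimate"` (the saliency estimator).
#' @param sal_params [saliency_params()] used when
#'   `wmap_source = "estimate"`.
#' @param verbose print one line per epoch.
#' @return object of class `wunet_fit`: list with `model`, `history`
#'   (one row per epoch), `best_epoch`.
#' @export
train_vessel_model <- function(clips, split, mconfig = model_config(),
                               tconfig = train_config(),
                               wmap_source = "ideal",
                               sal_params = saliency_params(),
                               verbose = FALSE) {
  vessels <- unique(vapply(clips, `[[`, "", "vessel_label"))
  if (length(vessels) != 1) {
    stop("clips mix vessel labels: ", paste(vessels, collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(split$train, split$test)) ||
      length(intersect(split$train, split$val)) ||
      length(intersect(split$val, split$test))) {
    stop("split partitions are not disjoint", call. = FALSE)
  }
  side <- mconfig$input_side
  arrays <- with_seed(tconfig$seed, list(
    train = assemble_arrays(clips, split$train, side, wmap_source,
                            sal_params),
    val = assemble_arrays(clips, split$val, side, wmap_source, sal_params)
  ))
  if (arrays$train$n == 0) {
    stop("training partition contains no frames", call. = FALSE)
  }
  # patient isolation assertion at loader construction
  test_patients <- vapply(
    Filter(function(cl) cl$patient_id %in% split$test, clips),
    `[[`, "", "patient_id")
  stopifnot(length(intersect(arrays$train$patients, test_patients)) == 0)

  model <- build_model(mconfig, seed = tconfig$seed)
  ntr <- arrays$train$n
  bs <- tconfig$batch_size
  history <- vector("list", tconfig$epochs)
  best <- list(dice = -Inf, epoch = 0L, weights = NULL)
  epoch_orders <- with_seed(tconfig$seed + 1L,
                            lapply(seq_len(tconfig$epochs),
                                   function(e) sample(ntr)))
  for (epoch in seq_len(tconfig$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- epoch_orders[[epoch]]
    losses <- c()
    for (s in seq(1, ntr, by = bs)) {
      idx <- ord[s:min(s + bs - 1, ntr)]
      losses <- c(losses, cpp_net_train_step(
        model$ptr,
        arrays$train$x[, , idx, drop = FALSE],
        arrays$train$w[, , idx, drop = FALSE],
        arrays$train$m[, , idx, drop = FALSE],
        tconfig$loss, tconfig$learning_rate, tconfig$beta1, tconfig$beta2,
        tconfig$adam_eps))
    }
    val <- if (arrays$val$n > 0) {
      eval_arrays(model, arrays$val, tconfig$loss)
    } else {
      list(dice = NA_real_, iou = NA_real_, loss = NA_real_)
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(losses), val_dice = val$dice,
      val_iou = val$iou, val_loss = val$loss,
      seconds = proc.time()[["elapsed"]] - t0)
    sel <- if (is.na(val$dice)) -mean(losses) else val$dice
    if (sel > best$dice) {
      best <- list(dice = sel, epoch = epoch, weights = model_weights(model))
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f", epoch,
                      mean(losses), val$dice))
    }
  }
  if (!is.null(best$weights)) set_model_weights(model, best$weights)
  structure(list(model = model, history = do.call(rbind, history),
                 best_epoch = best$epoch, vessel = vessels,
                 tconfig = tconfig), class = "wunet_fit")
}

#' @export
print.wunet_fit <- function(x, ...) {
  cat(sprintf("<wunet_fit> vessel %s, %d epochs, best epoch %d\n",
              x$vessel, nrow(x$history), x$best_epoch))
  invisible(x)
}
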