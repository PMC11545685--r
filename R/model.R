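# The weighted attention U-Net: configuration, construction, prediction.
#
# Encoder: five 3x3 conv stages with filters (32, 32, 64, 64, 128), ReLU,
# 2x2 max-pool between stages.  At levels 1..4 a weighted block fuses the
# max-pooled weight map w_l with the level's feature map: the map is lifted
# to the attention width by a 1x1 conv + ReLU, added element-wise to the
# (projected, max-pooled) features, refined by a 3x3 then 1x1 conv with a
# ReLU between, and squashed by a sigmoid into per-pixel gate coefficients
# X in [0, 1]; the gated skip is O_l = X * Q_l.  A symmetric decoder
# (upsample x2, concatenate O_l, two 3x3 convs + ReLU) and a 1x1 conv +
# sigmoid head produce a probability map at the input resolution.

#' Model configuration
#'
#' @param input_side input frame side in pixels (divisible by 16).
#' @param encoder_filters filter counts of the five encoder stages.
#' @param kernel_size convolution kernel side; the architecture uses 3.
#' @param attention_channels channel width of the weighted blocks; gated
#'   skips `O_l` carry this many channels.
#' @param decoder_filters filter counts of the four decoder stages
#'   (levels 4 down to 1).
#' @param head_channels width of the pre-head 3x3 convolution.
#' @param dropout_rate fixed at 0 (dropout is disabled by design).
#' @param output_channels single-channel probability output.
#' @return object of class `wunet_model_config`.
#' @export
model_config <- function(input_side = 256,
                         encoder_filters = c(32, 32, 64, 64, 128),
                         kernel_size = 3, attention_channels = 128,
                         decoder_filters = c(64, 64, 32, 32),
                         head_channels = 32, dropout_rate = 0,
                         output_channels = 1) {
  if (length(encoder_filters) != 5) {
    stop("encoder_filters must have length 5", call. = FALSE)
  }
  if (length(decoder_filters) != 4) {
    stop("decoder_filters must have length 4", call. = FALSE)
  }
  if (kernel_size != 3) stop("kernel_size must be 3", call. = FALSE)
  if (dropout_rate != 0) stop("dropout_rate is fixed at 0", call. = FALSE)
  if (output_channels != 1) {
    stop("only single-channel output is supported", call. = FALSE)
  }
  if (input_side %% 16 != 0 || input_side < 16) {
    stop("input_side must be a positive multiple of 16", call. = FALSE)
  }
  structure(list(input_side = as.integer(input_side),
                 encoder_filters = as.integer(encoder_filters),
                 kernel_size = 3L,
                 attention_channels = as.integer(attention_channels),
                 decoder_filters = as.integer(decoder_filters),
                 head_channels = as.integer(head_channels),
                 dropout_rate = 0, output_channels = 1L),
            class = "wunet_model_config")
}

# (cin, cout, k) per layer, in the engine's fixed layer order.
layer_dims <- function(config) {
  f <- config$encoder_filters
  a <- config$attention_channels
  d <- config$decoder_filters
  dims <- list(
    enc1 = c(1, f[1], 3), enc2 = c(f[1], f[2], 3), enc3 = c(f[2], f[3], 3),
    enc4 = c(f[3], f[4], 3), enc5 = c(f[4], f[5], 3))
  for (l in 1:4) {
    dims[[sprintf("wb%d_proj", l)]] <- c(f[l], a, 1)
    dims[[sprintf("wb%d_lift", l)]] <- c(1, a, 1)
    dims[[sprintf("wb%d_ref", l)]] <- c(a, a, 3)
    dims[[sprintf("wb%d_gate", l)]] <- c(a, 1, 1)
  }
  prev <- f[5]
  for (i in 1:4) {
    nm <- sprintf("dec%d", 5 - i)
    dims[[paste0(nm, "_a")]] <- c(prev + a, d[i], 3)
    dims[[paste0(nm, "_b")]] <- c(d[i], d[i], 3)
    prev <- d[i]
  }
  dims$head_a <- c(d[4], config$head_channels, 3)
  dims$head_b <- c(config$head_channels, 1, 1)
  dims
}

# He-uniform initialization for one conv layer.
init_conv <- function(cin, cout, k) {
  fan_in <- cin * k * k
  lim <- sqrt(6 / fan_in)
  list(W = matrix(runif(cout * fan_in, -lim, lim), cout, fan_in),
       b = rep(0, cout))
}

init_weights <- function(config, seed) {
  dims <- layer_dims(config)
  with_seed(seed, lapply(dims, function(d) init_conv(d[1], d[2], d[3])))
}

#' Build a weighted attention U-Net
#'
#' @param config a [model_config()].
#' @param seed seed of the (He-uniform) weight initialization.
#' @return object of class `wunet_model`.
#' @export
build_model <- function(config = model_config(), seed = 1) {
  weights <- init_weights(config, seed)
  ptr <- cpp_net_create(config, weights)
  structure(list(config = config, ptr = ptr, init_seed = seed),
            class = "wunet_model")
}

#' @export
print.wunet_model <- function(x, ...) {
  cat(sprintf(paste0("<wunet_model> input %dx%d, encoder (%s), attention ",
                     "width %d, %s parameters\n"),
              x$config$input_side, x$config$input_side,
              paste(x$config$encoder_filters, collapse = ", "),
              x$config$attention_channels,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `wunet_model`.
#' @export
n_parameters <- function(model) {
  cpp_net_param_count(model$ptr)
}

# Coerce frames/maps to an (H, W, N) array.
as_batch_array <- function(x, what = "frames") {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  if (length(dim(x)) != 3) {
    stop(what, " must be a matrix or (H, W, N) array", call. = FALSE)
  }
  x
}

#' Forward pass: per-pixel vessel probabilities
#'
#' @param model a `wunet_model`.
#' @param frames normalized frame(s) in \[0, 1\]: matrix or (H, W, N) array
#'   with square side divisible by 16.
#' @param wmaps weight map(s) of the same dimensions.  The model has no
#'   map-free mode; omitting them is an error.
#' @return (H, W, N) array of probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, frames, wmaps) {
  if (missing(wmaps) || is.null(wmaps)) {
    stop("weight maps are required: the model has no map-free mode",
         call. = FALSE)
  }
  frames <- as_batch_array(frames)
  wmaps <- as_batch_array(wmaps, "weight maps")
  if (!identical(dim(frames), dim(wmaps))) {
    stop("weight maps must match the frame dimensions", call. = FALSE)
  }
  cpp_net_forward(model$ptr, frames, wmaps)
}

#' Predict binary vessel masks
#'
#' @param object a `wunet_model`.
#' @param frames,wmaps as in [predict_prob()].
#' @param threshold probability cutoff; a pixel is vessel when
#'   `prob >= threshold`.
#' @param ... unused.
#' @return list with `prob` ((H, W, N) array) and `mask` (same shape,
#'   \{0,1\}).
#' @export
predict.wunet_model <- function(object, frames, wmaps, threshold = 0.5,
                                ...) {
  prob <- predict_prob(object, frames, wmaps)
  list(prob = prob, mask = (prob >= threshold) * 1)
}

#' One weighted block in isolation
#'
#' Exposes the attention unit for inspection: returns the gate coefficients
#' `X` (sigmoid output in \[0, 1\]), the max-pooled projected features `Q`
#' and the gated skip `O = X * Q`.
#'
#' @param lfm feature map, (H, W, C) array.
#' @param w weight map at the feature-map side (pooled internally) or
#'   already at half side (used as the pyramid level directly).
#' @param attention_channels block width used when `weights` is NULL.
#' @param weights optional named list (`proj`, `lift`, `ref`, `gate`) of
#'   `list(W, b)` conv parameters.
#' @param seed seed of the default random initialization.
#' @return list with `O` (h, w, attention_channels), `X` (h, w), `Q`.
#' @export
weighted_block <- function(lfm, w, attention_channels = 128, weights = NULL,
                           seed = 1) {
  if (length(dim(lfm)) != 3) stop("lfm must be an (H, W, C) array",
                                  call. = FALSE)
  h <- dim(lfm)[1]
  if (is.matrix(w) && nrow(w) == h) w <- cpp_maxpool2_mat(w)
  if (!is.matrix(w) || nrow(w) != h / 2) {
    stop("weight map side must equal the feature-map side or half of it",
         call. = FALSE)
  }
  if (min(w) < 0 || max(w) > 1) {
    stop("weight map values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(weights)) {
    cin <- dim(lfm)[3]
    a <- attention_channels
    weights <- with_seed(seed, list(
      proj = init_conv(cin, a, 1), lift = init_conv(1, a, 1),
      ref = init_conv(a, a, 3), gate = init_conv(a, 1, 1)))
  }
  cpp_weighted_block(lfm, w, weights)
}

#' Save or load a model checkpoint
#'
#' The checkpoint embeds the configuration, so [load_checkpoint()] rebuilds
#' the model without further arguments.
#'
#' @param model a `wunet_model`.
#' @param path checkpoint file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config),
               weights = cpp_net_get_weights(model$ptr),
               init_seed = model$init_seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  config <- do.call(model_config, x$config)
  ptr <- cpp_net_create(config, x$weights)
  structure(list(config = config, ptr = ptr, init_seed = x$init_seed),
            class = "wunet_model")
}

# Extract / restore raw weights (used for best-epoch checkpointing).
model_weights <- function(model) cpp_net_get_weights(model$ptr)

set_model_weights <- function(model, weights) {
  cpp_net_set_weights(model$ptr, weights)
  invisible(model)
}
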