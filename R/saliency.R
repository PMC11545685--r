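# Saliency weight maps: superpixel quadratic program and max-pool pyramid.
#
# The estimator scores superpixels, not pixels: a frame is partitioned into
# ~K SLIC superpixels, each of which receives a saliency s_k in [0, 1] by
# minimizing a convex quadratic objective; the scores are rasterized back to
# the pixel grid, lightly smoothed and min-max rescaled.

#' Parameters of the saliency weight-map estimator
#'
#' @param superpixels target number of SLIC superpixels.
#' @param compactness SLIC intensity tolerance; larger values weight spatial
#'   proximity more than intensity similarity.
#' @param lambda_smooth weight of the graph-Laplacian smoothness term that
#'   couples adjacent superpixels (connectedness prior).
#' @param lambda_center weight of the quadratic discount on superpixels far
#'   from the foreground centroid.
#' @param lambda_zero weight of the penalty for assigning zero saliency to
#'   strongly foreground-like superpixels.
#' @param polarity `"dark"` for anechoic (dark) targets such as vessel
#'   lumina; `"bright"` for echogenic targets.
#' @param smooth_sigma Gaussian sigma (pixels) of the final rasterized-map
#'   smoothing; 0 disables it.
#' @return object of class `wunet_saliency_params`.
#' @export
saliency_params <- function(superpixels = 200, compactness = 0.05,
                            lambda_smooth = 1, lambda_center = 0.5,
                            lambda_zero = 2, polarity = c("dark", "bright"),
                            smooth_sigma = 2) {
  polarity <- match.arg(polarity)
  structure(list(superpixels = superpixels, compactness = compactness,
                 lambda_smooth = lambda_smooth,
                 lambda_center = lambda_center, lambda_zero = lambda_zero,
                 polarity = polarity, smooth_sigma = smooth_sigma),
            class = "wunet_saliency_params")
}

# Bound-constrained quadratic program over superpixel saliencies, solved by
# projected gradient descent:
#   E(s) = ||s - f||^2 + lc * sum d_k s_k^2 + lz * sum g_k (s_k - 1)^2
#          + ls * s' L s ,   s in [0, 1]^K
# f: foreground likelihood, d: centroid-distance discount, g: indicator of
# strong foreground (zero-saliency cost), L: affinity graph Laplacian.
solve_saliency_qp <- function(f, d, g, Lmat, lambda_center, lambda_zero,
                              lambda_smooth, tol = 1e-6, maxit = 500) {
  lip <- 2 * (1 + lambda_center * max(d) + lambda_zero +
                lambda_smooth * 2 * max(diag(Lmat)))
  step <- 1 / lip
  s <- f
  for (it in seq_len(maxit)) {
    grad <- 2 * (s - f) + 2 * lambda_center * d * s +
      2 * lambda_zero * g * (s - 1) + 2 * lambda_smooth * (Lmat %*% s)[, 1]
    s_new <- clamp01(s - step * grad)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s
}

#' Estimate a saliency weight map for one normalized frame
#'
#' Produces the per-pixel prior the network consumes: values in \[0, 1\],
#' high where a pixel is likely to belong to a vessel.  Vessel lumina are
#' anechoic, so with the default `"dark"` polarity the foreground likelihood
#' is the (min-max normalized) inverted intensity, which also makes the map
#' invariant to positive affine rescaling of the input frame.
#'
#' @param frame normalized frame matrix, values in \[0, 1\].
#' @param params a [saliency_params()] object.
#' @return weight-map matrix in \[0, 1\] on the same grid as `frame`.
#' @export
estimate_weight_map <- function(frame, params = saliency_params()) {
  stopifnot_matrix(frame)
  if (diff(range(frame)) <= .Machine$double.eps) {
    warning("constant frame: returning a uniform weight map of 0.5")
    return(matrix(0.5, nrow(frame), ncol(frame)))
  }
  x <- rescale01(frame)
  labels <- cpp_slic(x, as.integer(params$superpixels),
                     params$compactness, 10L)
  k <- max(labels)
  idx <- as.vector(labels)
  npix <- tabulate(idx, k)
  mu <- tabulate_sum(idx, as.vector(x), k) / npix
  rows <- tabulate_sum(idx, as.vector(row(x)), k) / npix
  cols <- tabulate_sum(idx, as.vector(col(x)), k) / npix

  # (i) foreground likelihood per superpixel
  f <- if (params$polarity == "dark") rescale01(-mu) else rescale01(mu)
  # (ii) discount superpixels far from the foreground centroid
  ctr_r <- sum(f * rows) / max(sum(f), 1e-12)
  ctr_c <- sum(f * cols) / max(sum(f), 1e-12)
  d <- sqrt((rows - ctr_r)^2 + (cols - ctr_c)^2)
  d <- d / max(d, na.rm = TRUE)
  # (iii) zero-saliency cost on connected strong-foreground regions
  g <- as.numeric(f >= stats::quantile(f, 0.8))
  # Laplacian of the superpixel adjacency graph, intensity-affinity weighted
  adj <- superpixel_adjacency(labels, mu)
  Lmat <- diag(rowSums(adj)) - adj

  s <- solve_saliency_qp(f, d, g, Lmat, params$lambda_center,
                         params$lambda_zero, params$lambda_smooth)
  w <- matrix(s[idx], nrow(x), ncol(x))
  if (params$smooth_sigma > 0) w <- gaussian_blur(w, params$smooth_sigma)
  rescale01(w)
}

# Sum `values` within groups `idx` in 1..k.
tabulate_sum <- function(idx, values, k) {
  as.vector(rowsum(values, idx, reorder = TRUE))[
    match(seq_len(k), sort(unique(idx)))]
}

# Affinity-weighted adjacency between touching superpixels.
superpixel_adjacency <- function(labels, mu) {
  k <- max(labels)
  h <- nrow(labels)
  w <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-h, ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -w]), as.vector(labels[, -1]))
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  adj <- matrix(0, k, k)
  if (nrow(pairs)) {
    sig <- max(stats::sd(mu), 1e-6)
    a <- exp(-((mu[pairs[, 1]] - mu[pairs[, 2]])^2) / (2 * sig^2))
    for (i in seq_len(nrow(pairs))) {
      adj[pairs[i, 1], pairs[i, 2]] <- max(adj[pairs[i, 1], pairs[i, 2]], a[i])
      adj[pairs[i, 2], pairs[i, 1]] <- adj[pairs[i, 1], pairs[i, 2]]
    }
  }
  adj
}

#' Load a precomputed weight map from an image file
#'
#' First-class bypass for users who compute saliency maps with their own
#' machinery: 8-bit images are divided by 255; floating-point images are
#' clipped to \[0, 1\] with a warning when out of range.
#'
#' @param path PNG or TIFF file.
#' @param side optional target side; maps of a different size are resized
#'   bilinearly.
#' @return weight-map matrix in \[0, 1\].
#' @export
load_weight_map <- function(path, side = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported weight-map format: .", ext, call. = FALSE)
  }
  if (length(dim(x)) == 3) x <- x[, , 1]
  if (min(x) < 0 || max(x) > 1) {
    warning("weight map values outside [0, 1] were clipped")
    x <- clamp01(x)
  }
  if (!is.null(side) && (nrow(x) != side || ncol(x) != side)) {
    x <- clamp01(EBImage::imageData(EBImage::resize(EBImage::Image(x),
                                           w = side, h = side)))
  }
  x
}

#' Max-pool pyramid of a weight map
#'
#' Levels l = 1..4 obtained by repeated 2x2 stride-2 max pooling, matching
#' the scales at which the weighted blocks fuse the map into the encoder
#' (sides 128, 64, 32, 16 for a 256 x 256 map).
#'
#' @param w square weight-map matrix with side divisible by 16, values in
#'   \[0, 1\].
#' @return object of class `wunet_pyramid`: list of 4 matrices.
#' @export
build_pyramid <- function(w) {
  stopifnot_matrix(w, "weight map")
  if (nrow(w) != ncol(w) || nrow(w) %% 16 != 0) {
    stop("weight map must be square with side divisible by 16",
         call. = FALSE)
  }
  if (min(w) < 0 || max(w) > 1) {
    stop("weight map values must lie in [0, 1]", call. = FALSE)
  }
  levels <- vector("list", 4)
  cur <- w
  for (l in 1:4) {
    cur <- cpp_maxpool2_mat(cur)
    levels[[l]] <- cur
  }
  structure(list(levels = levels), class = "wunet_pyramid")
}
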