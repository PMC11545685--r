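# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Min-max rescale to [0, 1]; a constant input maps to all zeros.
rescale01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (rng[2] - rng[1] <= .Machine$double.eps) {
    return(array(0, dim = dim(x) %||% length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopifnot_matrix <- function(x, what = "frame") {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1 || ncol(x) < 1 ||
      anyNA(x)) {
    stop(sprintf("malformed %s: expected a non-empty numeric matrix", what),
         call. = FALSE)
  }
  invisible(x)
}

# An 8-bit raw frame: numeric matrix with values in [0, 255].
check_raw_frame <- function(x) {
  stopifnot_matrix(x, "raw frame")
  if (min(x) < 0 || max(x) > 255) {
    stop("raw frame values must lie within [0, 255]", call. = FALSE)
  }
  invisible(x)
}

# Strictly binary mask on {0, 1}.
check_binary_mask <- function(x, what = "mask") {
  stopifnot_matrix(x, what)
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("%s must be strictly {0,1}-valued", what), call. = FALSE)
  }
  invisible(x)
}

# Gaussian blur through EBImage, keeping plain-matrix in/out.
gaussian_blur <- function(x, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma))
}

vessel_vocabulary <- function() {
  c("IVC", "RHV", "MHV", "LHV", "MPV", "PV", "LPV", "RPV",
    "ARPV", "RAPV", "PRPV", "RPPV")
}
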