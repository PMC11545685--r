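# Seeded speckle phantom generator: IOUS-like clips with ground truth.
#
# A frame is rendered as dark elliptical vessel cross-sections on a brighter
# background, multiplied by gamma-distributed speckle (mean 1), optionally
# attenuated by a wedge-shaped acoustic shadow; vessel centers drift between
# frames to emulate probe motion, and frames are replaced by the three
# degenerate classes (black, vessel-absent, blurred) with configured
# probabilities.

#' Phantom generator configuration
#'
#' Defaults emulate a moderately difficult IOUS clip: anechoic lumina
#' (intensity 0.08) on a mid-gray background (0.55) under multiplicative
#' gamma speckle of shape 4, occasional acoustic shadows and slow probe
#' drift.  See [phantom_preset()] for the `easy`/`hard` study presets.
#'
#' @param image_side frame side in pixels.
#' @param n_vessels number of vessel cross-sections per clip.
#' @param vessel_radius_range min/max vessel semi-axis in pixels.
#' @param lumen_intensity,background_intensity mean intensities in \[0, 1\];
#'   the lumen must be darker than the background.
#' @param speckle_shape gamma shape of the multiplicative speckle (mean 1);
#'   larger is milder.
#' @param shadow_probability per-clip probability of an acoustic shadow.
#' @param black_frame_probability,no_target_probability,blur_probability
#'   per-frame probabilities of the three degenerate-frame classes.
#' @param blur_sigma Gaussian sigma (pixels) of the blur defect.
#' @param drift_px_per_frame vessel-center drift per frame (pixels).
#' @param frames_per_clip frames per generated clip.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `wunet_phantom_config`.
#' @export
phantom_config <- function(image_side = 256, n_vessels = 2,
                           vessel_radius_range = c(10, 24),
                           lumen_intensity = 0.08,
                           background_intensity = 0.55,
                           speckle_shape = 4, shadow_probability = 0.2,
                           black_frame_probability = 0,
                           no_target_probability = 0,
                           blur_probability = 0, blur_sigma = 8,
                           drift_px_per_frame = 0.5, frames_per_clip = 20,
                           seed = 1) {
  cfg <- structure(as.list(environment()), class = "wunet_phantom_config")
  if (lumen_intensity >= background_intensity) {
    stop("lumen_intensity must be below background_intensity", call. = FALSE)
  }
  probs <- c(shadow_probability, black_frame_probability,
             no_target_probability, blur_probability)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (max(vessel_radius_range) >= image_side / 2) {
    stop("vessel radius exceeds image side", call. = FALSE)
  }
  cfg
}

#' Study presets for the phantom generator
#'
#' `easy`: high contrast, mild speckle, no shadows and no defect frames --
#' the conditions used for training recovery checks.  `hard`: strong
#' speckle, shadows, fast drift and all three defect classes injected well
#' away from the quality-filter thresholds -- the conditions used for
#' filter-recovery and robustness checks.
#'
#' @param preset `"easy"` or `"hard"`.
#' @param image_side frame side in pixels.
#' @param ... overrides passed on to [phantom_config()].
#' @export
phantom_preset <- function(preset = c("easy", "hard"), image_side = 256,
                           ...) {
  preset <- match.arg(preset)
  r <- round(image_side * c(0.06, 0.12))
  base <- switch(preset,
    easy = list(image_side = image_side, n_vessels = 2,
                vessel_radius_range = r, lumen_intensity = 0.05,
                background_intensity = 0.6, speckle_shape = 8,
                shadow_probability = 0, drift_px_per_frame = 0.5),
    hard = list(image_side = image_side, n_vessels = 2,
                vessel_radius_range = r, lumen_intensity = 0.08,
                background_intensity = 0.55, speckle_shape = 4,
                shadow_probability = 0.5, black_frame_probability = 0.1,
                no_target_probability = 0.15, blur_probability = 0.15,
                drift_px_per_frame = 1.5)
  )
  do.call(phantom_config, utils::modifyList(base, list(...)))
}

# Render vessel geometry (soft-edged ellipses) and its binary mask.
render_vessels <- function(side, centers, axes, angles, lumen, bg) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)   # column index
  ys <- matrix(rep(seq_len(side), side), side, side)          # row index
  alpha <- matrix(0, side, side)
  mask <- matrix(0, side, side)
  for (i in seq_len(nrow(centers))) {
    dx <- xs - centers[i, 1]
    dy <- ys - centers[i, 2]
    ca <- cos(angles[i])
    sa <- sin(angles[i])
    u <- (dx * ca + dy * sa) / axes[i, 1]
    v <- (-dx * sa + dy * ca) / axes[i, 2]
    q <- sqrt(u^2 + v^2)
    edge <- 1.5 / min(axes[i, ])
    a <- clamp01((1 - q) / edge)
    alpha <- pmax(alpha, a)
    mask <- pmax(mask, (q <= 1) * 1)
  }
  list(base = bg - (bg - lumen) * alpha, mask = mask)
}

# Wedge-shaped acoustic shadow: attenuation fanning down from an apex.
shadow_field <- function(side, apex_col, apex_row, half_angle, strength) {
  xs <- matrix(rep(seq_len(side), each = side), side, side)
  ys <- matrix(rep(seq_len(side), side), side, side)
  below <- ys > apex_row
  spread <- abs(xs - apex_col) / pmax(ys - apex_row, 1)
  inside <- below & (spread < tan(half_angle))
  depth <- clamp01((ys - apex_row) / (side / 2))
  1 - strength * inside * depth
}

#' Generate one synthetic IOUS clip
#'
#' @param config a [phantom_config()] or [phantom_preset()] object.
#' @param patient_id,vessel_label,clip_id identifiers stamped on the clip.
#' @return a `wunet_clip` with 8-bit frames, \{0,1\} masks, ideal weight
#'   maps (smoothed true masks) and per-frame defect `labels`.
#' @export
generate_clip <- function(config = phantom_config(), patient_id = "P01",
                          vessel_label = "IVC", clip_id = "C001") {
  cfg <- config
  with_seed(cfg$seed, {
    side <- cfg$image_side
    nfr <- cfg$frames_per_clip
    # geometry: keep centers + drift path inside a safety margin
    total_drift <- cfg$drift_px_per_frame * (nfr - 1)
    margin <- max(cfg$vessel_radius_range) + 4
    lo <- margin + max(0, total_drift)
    hi <- side - margin - max(0, total_drift)
    if (lo >= hi) stop("drift path does not fit inside the frame",
                       call. = FALSE)
    nv <- cfg$n_vessels
    centers0 <- cbind(runif(nv, lo, hi), runif(nv, lo, hi))
    axes <- cbind(runif(nv, cfg$vessel_radius_range[1],
                        cfg$vessel_radius_range[2]), 0)
    axes[, 2] <- axes[, 1] * runif(nv, 0.7, 1.3)
    angles <- runif(nv, 0, pi)
    drift_angle <- runif(1, 0, 2 * pi)
    dvec <- cfg$drift_px_per_frame * c(cos(drift_angle), sin(drift_angle))
    has_shadow <- runif(1) < cfg$shadow_probability
    shadow <- if (has_shadow) {
      shadow_field(side, apex_col = runif(1, side * 0.2, side * 0.8),
                   apex_row = runif(1, 1, side * 0.3),
                   half_angle = runif(1, 0.1, 0.25), strength = 0.5)
    }

    frames <- masks <- wmaps <- vector("list", nfr)
    labels <- character(nfr)
    for (t in seq_len(nfr)) {
      centers <- sweep(centers0, 2, (t - 1) * dvec, `+`)
      u <- runif(1)
      p1 <- cfg$black_frame_probability
      p2 <- p1 + cfg$no_target_probability
      p3 <- p2 + cfg$blur_probability
      geom <- render_vessels(side, centers, axes, angles,
                             cfg$lumen_intensity, cfg$background_intensity)
      speckle <- matrix(rgamma(side * side, shape = cfg$speckle_shape,
                               rate = cfg$speckle_shape), side, side)
      if (u < p1) {                      # black frame; annotation unchanged
        img <- matrix(runif(side * side, 0, 4 / 255), side, side)
        labels[t] <- "blackness"
        mask <- geom$mask
      } else if (u < p2) {               # vessels absent from anatomy
        img <- cfg$background_intensity * speckle
        if (!is.null(shadow)) img <- img * shadow
        labels[t] <- "no_target"
        mask <- matrix(0, side, side)
      } else {
        img <- geom$base * speckle
        if (!is.null(shadow)) img <- img * shadow
        mask <- geom$mask
        if (u < p3) {
          img <- gaussian_blur(img, cfg$blur_sigma)
          labels[t] <- "blurry"
        } else {
          labels[t] <- "ok"
        }
      }
      frames[[t]] <- round(255 * clamp01(img))
      masks[[t]] <- mask
      wm <- if (sum(mask) > 0) {
        s <- gaussian_blur(mask, 3)
        clamp01(s / max(s))      # FFT blur can ring slightly negative
      } else {
        matrix(0, side, side)
      }
      wmaps[[t]] <- wm
    }
    clip_record(frames, masks, patient_id, vessel_label, clip_id,
                wmaps = wmaps, labels = labels)
  })
}

#' Generate a multi-patient phantom dataset on disk
#'
#' Writes the standard clip layout (`<root>/<patient>/<vessel>/<clip>/...`)
#' plus a `manifest.json` listing every frame with its defect label.
#' Per-clip sub-seeds are derived from the master seed so patients carry
#' statistically independent pixel data.
#'
#' @param root output directory.
#' @param n_patients number of patients (>= 3).
#' @param clips_per_patient clips per patient.
#' @param vessel_labels vessel labels cycled over clips.
#' @param config base [phantom_config()]; its seed acts as master seed.
#' @return (invisibly) the manifest as a list.
#' @export
generate_dataset <- function(root, n_patients, clips_per_patient = 2,
                             vessel_labels = "IVC",
                             config = phantom_config()) {
  if (n_patients < 3) stop("need at least 3 patients", call. = FALSE)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%02d", p)
    for (k in seq_len(clips_per_patient)) {
      sub <- config
      sub$seed <- (config$seed * 7919L + p * 1009L + k * 101L) %% 2147483647L
      vessel <- vessel_labels[(k - 1) %% length(vessel_labels) + 1]
      clip <- generate_clip(sub, patient_id = pid, vessel_label = vessel,
                            clip_id = sprintf("C%03d", k))
      write_clip(clip, root)
      files[[length(files) + 1]] <- data.frame(
        patient_id = pid, vessel_label = vessel, clip_id = clip$clip_id,
        frame_index = seq_along(clip$frames) - 1L,
        file = file.path(pid, vessel, clip$clip_id,
                         sprintf("frame_%05d.png",
                                 seq_along(clip$frames) - 1L)),
        label = clip$labels, stringsAsFactors = FALSE)
    }
  }
  manifest <- list(
    n_patients = n_patients, clips_per_patient = clips_per_patient,
    frames_per_clip = config$frames_per_clip, seed = config$seed,
    files = do.call(rbind, files))
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
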