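# Run configuration and the end-to-end pipeline:
# simulate -> preprocess -> train -> predict -> evaluate.

#' Merged run configuration
#'
#' Bundles the phantom, quality, saliency, model and training
#' configurations with the pipeline-level options, under a single global
#' seed.  The resolved configuration is serialized verbatim into every run
#' directory, which (with the seed) is sufficient to reproduce a run.
#'
#' @param seed global seed; module seeds are derived from it.
#' @param preset phantom preset (`"easy"` or `"hard"`).
#' @param n_patients,clips_per_patient,vessel_labels dataset shape.
#' @param phantom,quality,saliency,model,train module configurations;
#'   defaults are derived from `preset` and `seed`.
#' @param wmap_source weight maps used for training and inference:
#'   `"ideal"`, `"estimate"` or `"uniform"`.
#' @param threshold probability cutoff for predicted masks.
#' @param filter_quality drop defect frames before training.
#' @return object of class `wunet_run_config`.
#' @export
run_config <- function(seed = 7, preset = "easy", n_patients = 6,
                       clips_per_patient = 2, vessel_labels = "IVC",
                       phantom = NULL, quality = quality_thresholds(),
                       saliency = saliency_params(), model = NULL,
                       train = NULL, wmap_source = "ideal",
                       threshold = 0.5, filter_quality = TRUE) {
  side <- if (!is.null(model)) model$input_side else 128L
  if (is.null(phantom)) {
    phantom <- phantom_preset(preset, image_side = side, seed = seed)
  }
  if (is.null(model)) {
    model <- model_config(input_side = side, attention_channels = 32,
                          decoder_filters = c(32, 32, 16, 16),
                          head_channels = 16)
  }
  if (is.null(train)) {
    train <- train_config(epochs = 10, seed = seed)
  }
  train$seed <- as.integer(seed)
  phantom$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), preset = preset,
                 n_patients = n_patients,
                 clips_per_patient = clips_per_patient,
                 vessel_labels = vessel_labels, phantom = phantom,
                 quality = quality, saliency = saliency, model = model,
                 train = train, wmap_source = wmap_source,
                 threshold = threshold, filter_quality = filter_quality),
            class = "wunet_run_config")
}

# Serialize a run config to plain lists for YAML.
config_to_list <- function(cfg) {
  rapply(unclass(cfg), function(x) x, how = "replace")
}

write_run_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [run_config()] arguments; missing keys fall back to the
#' defaults.
#'
#' @param path YAML file.
#' @return a `wunet_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("seed", "preset", "n_patients", "clips_per_patient",
               "vessel_labels", "wmap_source", "threshold",
               "filter_quality")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_config, y$phantom)
  if (!is.null(y$quality)) args$quality <- do.call(quality_thresholds,
                                                   y$quality)
  if (!is.null(y$saliency)) args$saliency <- do.call(saliency_params,
                                                     y$saliency)
  if (!is.null(y$model)) args$model <- do.call(model_config, y$model)
  if (!is.null(y$train)) {
    tr <- y$train
    tr <- tr[setdiff(names(tr), c("optimizer", "augmentation"))]
    args$train <- do.call(train_config, tr)
  }
  do.call(run_config, args)
}

log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", file = log_path, append = TRUE)
  invisible(msg)
}

#' Run the full pipeline end to end
#'
#' Generates a phantom dataset, quality-filters it, makes a patient-level
#' split, trains one model per vessel label, predicts on held-out test
#' patients and writes `metrics.csv` with the per-vessel aggregate.  Fully
#' deterministic given the configuration seed: two runs with the same
#' config produce byte-identical `metrics.csv`.
#'
#' @param out_dir run directory (created, must be empty or absent).
#' @param config a [run_config()].
#' @return list with `metrics` (aggregate data.frame), `frames` (per-frame
#'   records), `run_dir`.
#' @export
run_end2end <- function(out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line(log_path, "wunet ", as.character(utils::packageVersion("wunet")),
           " end2end, seed ", config$seed)
  write_run_config(config, file.path(out_dir, "config_resolved.yaml"))
  writeLines(as.character(config$seed), file.path(out_dir, "seed.txt"))

  data_dir <- file.path(out_dir, "data")
  log_line(log_path, "simulate: ", config$n_patients, " patients")
  generate_dataset(data_dir, config$n_patients, config$clips_per_patient,
                   config$vessel_labels, config$phantom)

  clips <- lapply(list_clips(data_dir)$path, read_clip)
  report <- quality_report(clips, config$quality)
  write.csv(report, file.path(out_dir, "quality_report.csv"),
            row.names = FALSE)
  if (config$filter_quality) {
    clips <- lapply(clips, filter_clip, thresholds = config$quality)
    clips <- Filter(function(cl) length(cl$frames) > 0, clips)
  }
  patients <- sort(unique(vapply(clips, `[[`, "", "patient_id")))
  split <- make_patient_split(patients, seed = config$seed)
  write_split_manifest(split, file.path(out_dir, "split.json"))
  log_line(log_path, "split: ", length(split$train), "/",
           length(split$val), "/", length(split$test), " patients")

  all_frames <- list()
  for (vessel in unique(config$vessel_labels)) {
    vclips <- Filter(function(cl) cl$vessel_label == vessel, clips)
    if (!length(vclips)) next
    log_line(log_path, "train vessel ", vessel)
    fit <- train_vessel_model(vclips, split, config$model, config$train,
                              wmap_source = config$wmap_source,
                              sal_params = config$saliency)
    write.csv(fit$history,
              file.path(out_dir, sprintf("history_%s.csv", vessel)),
              row.names = FALSE)
    save_checkpoint(fit$model,
                    file.path(out_dir, sprintf("checkpoint_%s.rds", vessel)))
    test_arr <- with_seed(config$seed + 2L,
                          assemble_arrays(vclips, split$test,
                                          config$model$input_side,
                                          config$wmap_source,
                                          config$saliency))
    if (test_arr$n == 0) next
    prob <- predict_prob_batched(fit$model, test_arr$x, test_arr$w)
    for (i in seq_len(test_arr$n)) {
      all_frames[[length(all_frames) + 1]] <- frame_metrics(
        prob[, , i], test_arr$m[, , i], threshold = config$threshold,
        frame_id = i, vessel = vessel)
    }
  }
  frames <- do.call(rbind, all_frames)
  metrics <- aggregate_metrics(frames)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  log_line(log_path, "done: ", nrow(frames), " test frames")
  list(metrics = metrics, frames = frames, run_dir = out_dir)
}
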