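# Shared fixtures: tiny model configurations, small phantom corpora, and a
# memoized store so expensive training runs are computed once per session.

.wunet_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .wunet_test_cache)) {
    assign(key, compute(), envir = .wunet_test_cache)
  }
  get(key, envir = .wunet_test_cache)
}

# Small network for fast unit tests (not the study configuration).
tiny_mconfig <- function(side = 64) {
  model_config(input_side = side, encoder_filters = c(8, 8, 8, 8, 16),
               attention_channels = 8, decoder_filters = c(8, 8, 8, 8),
               head_channels = 8)
}

# Desk-scale study configuration used by the training recovery runs:
# full encoder filter complement, reduced attention/decoder width, 128 px.
study_mconfig <- function() {
  model_config(input_side = 128, encoder_filters = c(32, 32, 64, 64, 128),
               attention_channels = 8, decoder_filters = c(8, 8, 8, 8),
               head_channels = 8)
}

# An in-memory multi-patient easy-preset corpus of one vessel.
make_corpus <- function(n_patients, clips_per_patient = 2,
                        frames_per_clip = 25, side = 128, seed = 31,
                        preset = "easy") {
  clips <- list()
  for (p in seq_len(n_patients)) {
    for (k in seq_len(clips_per_patient)) {
      cfg <- phantom_preset(preset, image_side = side,
                            frames_per_clip = frames_per_clip,
                            seed = (seed * 7919L + p * 1009L +
                                      k * 101L) %% 2147483647L)
      clips[[length(clips) + 1]] <- generate_clip(
        cfg, patient_id = sprintf("P%02d", p), vessel_label = "IVC",
        clip_id = sprintf("C%03d", k))
    }
  }
  clips
}

# The 12-patient 8/1/3 protocol: 400 train frames at 128 px, 30 epochs,
# batch 16, Adam lr 0.001.  Memoized; the ablation run reuses the corpus
# and split with uniform-random weight maps instead of ideal ones.
recovery_protocol <- function() {
  cache_get("recovery_inputs", function() {
    clips <- make_corpus(12, 2, 25, 128, seed = 31)
    pats <- sprintf("P%02d", 1:12)
    perm <- withr::with_seed(31, sample(pats))
    split <- structure(list(train = sort(perm[1:8]), val = sort(perm[9]),
                            test = sort(perm[10:12])),
                       class = "wunet_split")
    list(clips = clips, split = split)
  })
}

recovery_run <- function(wmap_source = "ideal") {
  cache_get(paste0("recovery_", wmap_source), function() {
    inp <- recovery_protocol()
    tcfg <- train_config(epochs = 30, seed = 31)
    fit <- train_vessel_model(inp$clips, inp$split, study_mconfig(), tcfg,
                              wmap_source = wmap_source)
    test_arr <- withr::with_seed(77, wunet:::assemble_arrays(
      inp$clips, inp$split$test, 128, wmap_source))
    ev <- wunet:::eval_arrays(fit$model, test_arr)
    list(fit = fit, heldout = ev)
  })
}
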