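# The speckle phantom generator.

test_that("generation is fully deterministic given the seed", {
  cfg <- phantom_preset("hard", image_side = 64, frames_per_clip = 6,
                        seed = 5)
  c1 <- generate_clip(cfg, patient_id = "P01")
  c2 <- generate_clip(cfg, patient_id = "P01")
  expect_identical(c1$frames, c2$frames)
  expect_identical(c1$masks, c2$masks)
  expect_identical(c1$labels, c2$labels)
  c3 <- generate_clip(phantom_preset("hard", image_side = 64,
                                     frames_per_clip = 6, seed = 6),
                      patient_id = "P01")
  expect_false(identical(c1$frames, c3$frames))
})

test_that("forced black frames are labeled and nearly dark", {
  cfg <- phantom_config(image_side = 64, vessel_radius_range = c(4, 8),
                        black_frame_probability = 1, frames_per_clip = 5,
                        seed = 3)
  clip <- generate_clip(cfg, patient_id = "P01")
  expect_true(all(clip$labels == "blackness"))
  for (f in clip$frames) expect_lt(mean(f / 255), 0.05)
})

test_that("vessel drift moves the mask centroid by drift * (n-1)", {
  cfg <- phantom_config(image_side = 128, n_vessels = 1,
                        vessel_radius_range = c(8, 12),
                        drift_px_per_frame = 2, frames_per_clip = 10,
                        shadow_probability = 0, seed = 9)
  clip <- generate_clip(cfg, patient_id = "P01")
  centroid <- function(m) {
    c(sum(row(m) * m), sum(col(m) * m)) / sum(m)
  }
  d <- centroid(clip$masks[[10]]) - centroid(clip$masks[[1]])
  expect_equal(sqrt(sum(d^2)), 18, tolerance = 1 / 18)
})

test_that("lumen is darker than background and mask area is plausible", {
  cfg <- phantom_preset("easy", image_side = 128, frames_per_clip = 4,
                        seed = 12)
  clip <- generate_clip(cfg, patient_id = "P01")
  for (i in seq_along(clip$frames)) {
    f <- clip$frames[[i]] / 255
    m <- clip$masks[[i]]
    expect_gt(mean(f[m == 0]) - mean(f[m == 1]), 0.2)
    # area within geometric bounds (2 vessels, radii 8..15, ellipse
    # aspect 0.7..1.3) with rasterization slack
    expect_gt(mean(m), 0.5 * pi * 8 * 0.7 * 8 / (128 * 128))
    expect_lt(mean(m), 2 * pi * 15 * 1.3 * 15 / (128 * 128) * 1.05)
  }
})

test_that("ideal weight maps track the mask and stay in [0,1]", {
  clip <- generate_clip(phantom_preset("easy", image_side = 64,
                                       frames_per_clip = 3, seed = 4),
                        patient_id = "P01")
  for (i in 1:3) {
    w <- clip$wmaps[[i]]
    m <- clip$masks[[i]]
    expect_true(min(w) >= 0 && max(w) <= 1)
    expect_gt(mean(w[m == 1]), mean(w[m == 0]))
  }
})

test_that("dataset generation writes the clip layout and manifest", {
  root <- withr::local_tempdir()
  man <- generate_dataset(root, n_patients = 3, clips_per_patient = 2,
                          vessel_labels = c("IVC", "RHV"),
                          config = phantom_config(image_side = 32,
                                                  vessel_radius_range = c(3, 5),
                                                  frames_per_clip = 3,
                                                  drift_px_per_frame = 0.2,
                                                  seed = 7))
  expect_length(list.dirs(root, recursive = FALSE), 3)
  expect_equal(nrow(man$files), 3 * 2 * 3)
  expect_true(file.exists(file.path(root, "manifest.json")))
  # round trip through the reader
  clips <- lapply(list_clips(root)$path, read_clip)
  expect_length(clips, 6)
  expect_setequal(vapply(clips, `[[`, "", "vessel_label"), c("IVC", "RHV"))
  cl <- clips[[1]]
  expect_length(cl$frames, 3)
  expect_false(is.null(cl$wmaps))
  # different patients carry different pixel data (independent sub-seeds)
  expect_false(identical(clips[[1]]$frames, clips[[3]]$frames))
  expect_error(generate_dataset(withr::local_tempdir(), 2),
               "3 patients")
})

test_that("vessel radius exceeding the frame is rejected", {
  expect_error(phantom_config(image_side = 64,
                              vessel_radius_range = c(10, 40)),
               "radius")
})
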