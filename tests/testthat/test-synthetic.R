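test_that("config validation rejects impossible geometry", {
  expect_error(tiny_cfg(n_controls = 1L), "n_controls")
  expect_error(tiny_cfg(brain_radii_mm = c(30, 30, 30)), "grid too small")
  expect_error(tiny_cfg(lesion_radius_range_mm = c(5, 3)), "ordered")
  expect_error(tiny_cfg(effect_per_task = c(gesture_production = -1,
                                            gesture_recognition = 3,
                                            gesture_imitation = 6)),
               "effect_per_task")
})

test_that("zero-noise control volume is exactly the analytic phantom", {
  cfg <- tiny_cfg(parenchyma_sd = 0, csf_sd = 0)
  v <- generate_control_volume(cfg)
  anat <- praxismap:::sim_anatomy(cfg)
  paren <- anat$brain > 0 & anat$ventricles == 0
  expect_true(all(v$data[paren] == cfg$parenchyma_mean))
  expect_true(all(v$data[anat$ventricles > 0] == cfg$csf_mean))
  expect_true(all(v$data[anat$brain == 0] == 0))
})

test_that("control generation is deterministic given the RNG state", {
  cfg <- tiny_cfg()
  set.seed(7); a <- generate_control_volume(cfg)
  set.seed(7); b <- generate_control_volume(cfg)
  expect_identical(a$data, b$data)
})

test_that("brain-voxel intensity histogram is bimodal at the tissue means", {
  cfg <- sim_config(n_controls = 2L, n_patients = 0L)  # default 48^3 phantom
  set.seed(2)
  v <- generate_control_volume(cfg)
  anat <- praxismap:::sim_anatomy(cfg)
  paren <- v$data[anat$brain > 0 & anat$ventricles == 0]
  vent <- v$data[anat$ventricles > 0]
  expect_equal(mean(paren), 40, tolerance = 0.01)
  expect_equal(mean(vent), 10, tolerance = 0.05)
  expect_equal(sd(paren), 2, tolerance = 0.1)
  # the pooled histogram is bimodal: global mode at the parenchyma level and
  # a second, local mode at the CSF level
  brain_vals <- v$data[anat$brain > 0]
  h <- hist(brain_vals, breaks = seq(min(brain_vals) - 1, max(brain_vals) + 1, 0.5),
            plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - 40), 2)
  low <- h$mids < 25
  expect_lt(abs(h$mids[low][which.max(h$counts[low])] - 10), 2)
  # and the trough between the modes is well below both peaks
  mid <- h$mids >= 20 & h$mids <= 30
  expect_lt(max(h$counts[mid]), max(h$counts[low]) / 2)
})

test_that("lesion shifts intensity by the configured amount", {
  cfg <- sim_config(n_controls = 2L, n_patients = 1L, seed = 4)
  set.seed(4)
  pat <- generate_patient_volume(cfg)
  anat <- praxismap:::sim_anatomy(cfg)
  in_paren <- pat$lesion$data > 0 & anat$ventricles == 0
  expect_gt(sum(in_paren), 100)
  expect_equal(mean(pat$image$data[in_paren]),
               cfg$parenchyma_mean + cfg$lesion_intensity_shift,
               tolerance = 0.3)
})

test_that("a fixed-radius lesion voxelises to the analytic sphere volume", {
  cfg <- sim_config(lesion_radius_range_mm = c(5, 5), n_controls = 2L,
                    n_patients = 1L)
  set.seed(9)
  pat <- generate_patient_volume(cfg)
  expect_equal(sum(pat$lesion$data), 4 / 3 * pi * 5^3, tolerance = 0.05)
})

test_that("zero-shift patients follow the control law but still carry truth", {
  cfg <- tiny_cfg(lesion_intensity_shift = 0)
  set.seed(5)
  pat <- generate_patient_volume(cfg)
  set.seed(5)
  ctrl <- generate_control_volume(cfg)
  expect_identical(pat$image$data, ctrl$data)
  expect_gt(sum(pat$lesion$data), 0)
})

test_that("behavioural scores follow the overlap model exactly when noiseless", {
  cfg <- tiny_cfg(noise_sd_behavior = 0,
                  effect_per_task = c(gesture_production = 8,
                                      gesture_recognition = 4,
                                      gesture_imitation = 8))
  age <- cfg$age_mean
  expect_equal(unname(generate_behavior(0, age, cfg)), c(12, 6, 12))
  expect_equal(unname(generate_behavior(0.5, age, cfg)), c(8, 4, 8))
  cfg_floor <- tiny_cfg(noise_sd_behavior = 0,
                        effect_per_task = c(gesture_production = 12,
                                            gesture_recognition = 6,
                                            gesture_imitation = 12))
  expect_equal(unname(generate_behavior(1, age, cfg_floor)), c(0, 0, 0))
  expect_error(generate_behavior(1.2, age, cfg), "overlap")
})

test_that("scores stay on the integer grid inside the task ranges", {
  cfg <- tiny_cfg(noise_sd_behavior = 3)
  set.seed(8)
  maxima <- task_maxima()[names(cfg$effect_per_task)]
  for (i in 1:50) {
    s <- generate_behavior(runif(1), runif(1, 30, 95), cfg)
    expect_true(all(s == round(s)))
    expect_true(all(s >= 0 & s <= maxima))
  }
})

test_that("cohort generation is reproducible and respects the demography", {
  cfg <- tiny_cfg(n_patients = 6L, seed = 21L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$patients[[3]]$data, b$patients[[3]]$data)
  expect_equal(nrow(a$behavior), 6L)
  expect_length(a$controls, cfg$n_controls)
  expect_true(all(a$behavior$age_years >= 27 & a$behavior$age_years <= 94))
})

test_that("a large cohort reproduces the target mean age", {
  cfg <- tiny_cfg(grid_shape = c(16L, 16L, 16L), brain_radii_mm = c(6, 7, 6),
                  ventricle_radii_mm = c(1.5, 2, 1.5), ventricle_offset_mm = 2.5,
                  lesion_radius_range_mm = c(2, 3),
                  n_controls = 2L, n_patients = 387L, seed = 13L)
  co <- generate_cohort(cfg)
  expect_equal(mean(co$behavior$age_years), 72.39,
               tolerance = 2 / 72.39)  # within 3 SE of the target
  expect_gt(mean(co$behavior$handedness == "R"), 0.85)
})

test_that("empty patient list still yields a valid control set", {
  cfg <- tiny_cfg(n_patients = 0L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$behavior), 0L)
  expect_length(co$patients, 0L)
  expect_length(co$controls, cfg$n_controls)
})

test_that("ground-truth overlap fractions are exactly recomputable from masks", {
  cfg <- tiny_cfg(n_patients = 5L, seed = 31L)
  co <- generate_cohort(cfg)
  crit <- co$truth$critical_region$data
  for (i in seq_len(5)) {
    rec <- sum(co$truth$lesions[[i]]$data * crit) / sum(crit)
    expect_identical(co$truth$overlap[i], rec)
  }
})
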