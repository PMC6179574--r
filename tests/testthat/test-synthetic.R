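test_that("generator configuration is validated", {
  expect_error(generator_config(n_subjects = 0), "positive")
  expect_error(generator_config(eye_dipole_gain = -1), "non-negative")
  expect_error(generator_config(noise_spatial_corr = 1), "\\[0, 1\\)")
  expect_s3_class(test_cfg(), "generator_config")
})

test_that("task generation honors the design and is seed-deterministic", {
  cfg <- test_cfg()
  task <- generate_task_data(cfg)
  # trial count: n_trials_per_cell x 8 cells x blocks
  expect_equal(n_trials(task$meg), 3 * 8 * 3)
  tt <- task$meg$trials
  expect_equal(sort(unique(tt$rotation_deg)), c(0, 60, 120, 180))
  expect_equal(sort(unique(tt$stimulus_orientation_deg)), c(15, 75, 135))
  expect_equal(unname(table(tt$stimulus_orientation_deg)),
               rep(24, 3), ignore_attr = TRUE)
  # every design cell equally filled
  expect_true(all(table(tt$rotation_deg, tt$direction) == 9))
  # epoch covers cue baseline through probe
  expect_lt(task$meg$times[1], -1.034)
  expect_gte(max(task$meg$times), 0.217 + cfg$delay_s)
  # determinism
  task2 <- generate_task_data(cfg)
  expect_identical(task$meg$data, task2$meg$data)
  expect_identical(task$gaze$data, task2$gaze$data)
  expect_identical(task$truth$subjects, task2$truth$subjects)
  # different seed changes the data
  task3 <- generate_task_data(test_cfg(seed = 43))
  expect_false(identical(task$meg$data, task3$meg$data))
})

test_that("localizer uses six orientations with the configured trial count", {
  cfg <- test_cfg()
  loc <- generate_localizer_data(cfg)
  expect_equal(n_trials(loc$meg), 6 * 24)
  expect_equal(sort(unique(loc$meg$trials$stimulus_orientation_deg)),
               seq(15, 165, 30))
  expect_true(all(table(loc$meg$trials$stimulus_orientation_deg) == 24))
  # defaults: 120 trials per orientation -> 720 trials
  expect_equal(generator_config()$n_localizer_trials_per_orientation * 6,
               720)
  # localizer gaze carries no stimulus information (pure noise at fixation)
  g <- loc$gaze$data
  expect_lt(abs(mean(g)), 0.02)
  byori <- sapply(split(seq_len(n_trials(loc$gaze)),
                        loc$gaze$trials$stimulus_orientation_deg),
                  function(i) mean(g[i, 1, ]))
  expect_lt(diff(range(byori)), 0.05)
})

test_that("orientation patterns live on the doubled circle", {
  p15 <- orientation_pattern(15, 32, subject_seed = 9)
  p105 <- orientation_pattern(105, 32, subject_seed = 9)
  # 90 degrees apart -> doubled angles antipodal -> anti-correlated
  expect_equal(p105, -p15, tolerance = 1e-12)
  # continuity
  p16 <- orientation_pattern(16, 32, subject_seed = 9)
  expect_lt(max(abs(p16 - p15)), 0.05)
  # orthonormal mixing: norm independent of orientation
  norms <- apply(orientation_pattern(seq(0, 175, 5), 32, 9), 2,
                 function(v) sqrt(sum(v^2)))
  expect_lt(diff(range(norms)), 1e-12)
  expect_error(orientation_pattern(180, 32, 9), "\\[0, 180\\)")
})

test_that("gaze drifts along the stimulus orientation axis and saturates", {
  # delay of 3 s so a 180-degree rotation has time to pass the saturation
  # angle (60 deg at 30 deg/s, starting 0.3 s post-stimulus)
  cfg <- test_cfg(gaze_amplitude_deg = 1, gaze_noise_sd = 0.02,
                  eye_dipole_gain = 0, delay_s = 3)
  task <- generate_task_data(cfg)
  g <- task$gaze
  sel <- g$times >= 0.5 & g$times <= 1.5
  pos <- apply(g$data[, , sel], c(1, 2), mean)
  # in the VWM (0 deg) condition the mean position lies on the stimulus axis
  vwm <- g$trials$rotation_deg == 0
  ang <- atan2(pos[vwm, 1], pos[vwm, 2]) * 180 / pi
  expect_lt(max(orientation_distance(
    ang, g$trials$stimulus_orientation_deg[vwm])), 10)
  # distance from fixation approximates the configured amplitude
  expect_equal(mean(sqrt(rowSums(pos[vwm, ]^2))), 1, tolerance = 0.1)
  # saturation: late gaze in the 180-degree condition sits at +/-60 from
  # the start orientation, not at the (equal) target orientation axis angle
  late <- g$times >= 0.217 + cfg$delay_s - 0.3
  posl <- apply(task$truth$gaze_latent[, , late], c(1, 2), mean)
  r180 <- which(g$trials$rotation_deg == 180)
  angl <- atan2(posl[r180, 1], posl[r180, 2]) * 180 / pi
  expect_lt(max(orientation_distance(
    angl, g$trials$stimulus_orientation_deg[r180] +
      ifelse(g$trials$direction[r180] == "CW", 60, -60))), 1)
})

test_that("zero-signal world yields chance-level gaze decoding", {
  cfg <- test_cfg(gaze_amplitude_deg = 0, eye_dipole_gain = 0)
  task <- generate_task_data(cfg)
  gaze <- smooth_moving_average(
    baseline_correct(task$gaze, c(-0.2, 0), "cue"), 0.1)
  # decode at a sparse grid of time points to keep this light
  keep <- seq(1, length(gaze$times), by = 8)
  sub <- epoch_set(gaze$data[, , keep], gaze$times[keep],
                   gaze$feature_labels, gaze$trials)
  tg <- crossval_temporal_generalization(sub, lambda = 0.01, seed = 3)
  true_class <- dplyr::filter(tg, rel_offset_deg == 0)
  expect_equal(
    sum(true_class$posterior * true_class$n_trials) /
      sum(true_class$n_trials),
    1 / 3, tolerance = 0.02)
})
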