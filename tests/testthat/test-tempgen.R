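test_that("generalization surface sits at chance for label-independent data", {
  set.seed(31)
  e <- make_epochs(array(rnorm(48 * 5 * 3), c(48, 5, 3)),
                   times = c(0, 0.1, 0.2))
  tg <- crossval_temporal_generalization(e, labels = rep(1:3, 16),
                                         folds = 8, lambda = 0.05, seed = 1)
  expect_named(tg, c("train_time", "test_time", "posterior", "n_trials"))
  expect_equal(attr(tg, "chance"), 1 / 3)
  expect_equal(mean(tg$posterior), 1 / 3, tolerance = 0.05)
  expect_error(
    crossval_temporal_generalization(e, labels = rep(1:3, 16), folds = 20),
    "at least")
})

test_that("transient signal generalizes on the diagonal, not off it", {
  cfg <- test_cfg(eye_dipole_gain = 0, gaze_amplitude_deg = 0,
                  neural_transient_gain = 1.5)
  task <- generate_task_data(cfg)
  meg <- smooth_moving_average(baseline_correct(task$meg), 0.1)
  tg <- crossval_temporal_generalization(meg, lambda = 0.05, seed = 5)
  on_diag <- dplyr::filter(tg, rel_offset_deg == 0,
                           train_time > 0.05, train_time < 0.4,
                           abs(train_time - test_time) < 0.026)
  off_diag <- dplyr::filter(tg, rel_offset_deg == 0,
                            train_time > 0.05, train_time < 0.4,
                            test_time > 1, test_time < 2)
  expect_gt(mean(on_diag$posterior), 0.6)
  expect_lt(mean(off_diag$posterior), 0.4)
  expect_gt(mean(on_diag$posterior), mean(off_diag$posterior))
})

test_that("condition profiles average training rows as specified", {
  # constant surface -> constant profile; single-row window -> that row
  tt <- c(0, 0.1, 0.2)
  tg <- tidyr::expand_grid(train_time = tt, test_time = tt,
                           rotation_deg = c(0, 60),
                           rel_offset_deg = c(0, 60, 120))
  tg$posterior <- 0.4
  tg$n_trials <- 10
  tg <- structure(tg, chance = 1 / 3, measure = "posterior",
                  class = c("tg_tbl", class(tg)))
  pr <- condition_profiles(tg, c(0, 0.2), target = "presented")
  expect_true(all(pr$posterior == 0.4))
  expect_equal(nrow(pr), 6)  # 2 conditions x 3 test times

  tg$posterior <- seq_len(nrow(tg))  # distinct values per row
  pr1 <- condition_profiles(tg, c(0.1, 0.1), target = "all")
  manual <- dplyr::filter(tg, train_time == 0.1)
  expect_equal(
    dplyr::arrange(pr1, rotation_deg, rel_offset_deg, test_time)$posterior,
    dplyr::arrange(manual, rotation_deg, rel_offset_deg,
                   test_time)$posterior)
  expect_error(condition_profiles(tg, c(5, 6)), "no training")

  # target selection: rotation 0 and 180 map to offset 0, 60 to 60
  tg2 <- tidyr::expand_grid(train_time = 0, test_time = 0,
                            rotation_deg = c(0, 60, 120, 180),
                            rel_offset_deg = c(0, 60, 120))
  tg2$posterior <- 0.5; tg2$n_trials <- 1
  tg2 <- structure(tg2, class = c("tg_tbl", class(tg2)))
  sel <- condition_profiles(tg2, c(0, 0), target = "target")
  expect_equal(dplyr::arrange(sel, rotation_deg)$rel_offset_deg,
               c(0, 60, 120, 0))
})

test_that("spatial patterns are difference ERFs with zero class sum", {
  set.seed(12)
  times <- seq(0, 0.3, 0.1)
  # identical classes -> zero patterns
  e0 <- make_epochs(array(1, c(12, 4, 4)), times,
                    make_trials(rep(c(15, 75, 135), 4)))
  sp0 <- spatial_pattern(e0, time_window = c(0, 0.3))
  expect_equal(max(abs(sp0$pattern)), 0)
  # balanced classes: per-feature sum of class patterns == 0
  e1 <- make_epochs(array(rnorm(12 * 4 * 4), c(12, 4, 4)), times,
                    make_trials(rep(c(15, 75, 135), 4)))
  sp1 <- spatial_pattern(e1, time_window = c(0, 0.3))
  sums <- dplyr::summarise(dplyr::group_by(sp1, feature),
                           s = sum(pattern))$s
  expect_lt(max(abs(sums)), 1e-10)
  # unbalanced classes warn
  e2 <- make_epochs(array(rnorm(10 * 4 * 4), c(10, 4, 4)), times,
                    make_trials(rep(c(15, 75, 135), c(4, 3, 3))))
  expect_warning(spatial_pattern(e2, time_window = c(0, 0.3)), "unbalanced")
})

test_that("confound-world patterns concentrate on the dipole topography", {
  cfg <- test_cfg(neural_transient_gain = 0, eye_dipole_gain = 1.5,
                  gaze_amplitude_deg = 0.8, noise_sd = 0.15)
  task <- generate_task_data(cfg)
  meg <- smooth_moving_average(baseline_correct(task$meg), 0.1)
  sp <- spatial_pattern(meg, time_window = c(0.5, 1.5))
  strength <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(sp, feature),
                     s = sqrt(mean(pattern^2)), .groups = "drop"),
    feature)  # labels are zero-padded, so this is sensor order
  G <- task$truth$mixing[[1]]$G
  expect_gt(cor(strength$s, sqrt(rowSums(G^2))), 0.7)
})
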