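#' Configuration for the synthetic MEG + gaze generator
#'
#' Builds the parameter list consumed by [generate_task_data()] and
#' [generate_localizer_data()]. Defaults reproduce the design of the combined
#' working-memory / mental-rotation experiment the package emulates: a cue at
#' -0.834 s (417 ms cue + 417 ms blank), a 217 ms grating drawn from
#' \{15, 75, 135\} degrees, an 8.017 s retention delay, rotation conditions
#' \{0, 60, 120, 180\} degrees crossed with \{CW, CCW\}, three trials per
#' design cell per block and six blocks (144 trials), plus a six-orientation
#' functional localizer (15 to 165 degrees in steps of 30, 250 ms stimuli,
#' 120 trials per orientation).
#'
#' The confound structure follows the eyeball-dipole mechanism: after
#' stimulus encoding, gaze drifts a fraction of a degree of visual angle away
#' from fixation along the remembered grating's orientation axis, tracks
#' mental rotation at 30 deg/s but saturates at +/-60 degrees from the start
#' orientation, and the (measured) gaze couples linearly into the sensors
#' through a frontal-weighted dipole mixing matrix. Subject-mean gaze drift
#' amplitudes are drawn log-normally so they span roughly 0.05 to 1.5 degrees
#' across subjects, matching the order of magnitude reported for real
#' observers.
#'
#' The sensor count (64) and sampling rate (120 Hz) are scaled-down
#' stand-ins for a 275-sensor, 1200 Hz acquisition; all sizes can be raised.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_trials_per_cell trials per rotation-by-direction design cell per
#'   block.
#' @param n_blocks number of task blocks.
#' @param n_sensors number of MEG-like sensors.
#' @param sample_rate_hz sampling rate in Hz.
#' @param delay_s retention-delay duration in seconds (probe onset is at
#'   `0.217 + delay_s`).
#' @param neural_transient_gain amplitude of the stimulus-evoked
#'   orientation-tuned sensor pattern (active roughly 0 to 0.5 s).
#' @param neural_sustained_gain amplitude of a genuinely neural sustained
#'   orientation pattern through the delay; the default 0 is the
#'   "confound-only" world in which any delay decoding must come from gaze.
#' @param eye_dipole_gain coupling strength of the eyeball dipole into the
#'   sensors.
#' @param gaze_amplitude_deg subject-mean gaze drift amplitude in degrees
#'   visual angle; a scalar applies to all subjects, `NULL` draws per-subject
#'   amplitudes log-normally (median 0.25, spanning ~0.05-1.5).
#' @param gaze_saturation_deg maximal rotation of the gaze-tracked
#'   orientation away from the start orientation, degrees.
#' @param rotation_speed_deg_per_s mental-rotation speed.
#' @param drift_onset_s time after stimulus onset at which the gaze drift
#'   (and mental rotation) begins. The analyses only constrain this loosely
#'   (decoding rises around 0.5 s); 0.3 s is a free choice, not a data claim.
#' @param noise_spatial_corr lag-one spatial correlation of the sensor noise
#'   (exponentially decaying across sensor index), in \[0, 1).
#' @param noise_sd sensor noise standard deviation.
#' @param gaze_noise_sd gaze measurement noise standard deviation, degrees.
#' @param n_localizer_trials_per_orientation localizer trials per orientation.
#' @param confound_overlap if `FALSE` (default) the dipole mixing matrix is
#'   orthogonalized against the neural orientation mixing, so decoders
#'   trained on genuinely neural patterns are exactly blind to the gaze
#'   artifact; `TRUE` leaves the two subspaces overlapping for realism
#'   studies.
#' @param seed integer seed; fully determines all generated data.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 24,
                             n_trials_per_cell = 3,
                             n_blocks = 6,
                             n_sensors = 64,
                             sample_rate_hz = 120,
                             delay_s = 8.017,
                             neural_transient_gain = 1,
                             neural_sustained_gain = 0,
                             eye_dipole_gain = 1,
                             gaze_amplitude_deg = NULL,
                             gaze_saturation_deg = 60,
                             rotation_speed_deg_per_s = 30,
                             drift_onset_s = 0.3,
                             noise_spatial_corr = 0.5,
                             noise_sd = 0.3,
                             gaze_noise_sd = 0.1,
                             n_localizer_trials_per_orientation = 120,
                             confound_overlap = FALSE,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_cell = as.integer(n_trials_per_cell),
    n_blocks = as.integer(n_blocks),
    n_sensors = as.integer(n_sensors),
    sample_rate_hz = sample_rate_hz,
    delay_s = delay_s,
    neural_transient_gain = neural_transient_gain,
    neural_sustained_gain = neural_sustained_gain,
    eye_dipole_gain = eye_dipole_gain,
    gaze_amplitude_deg = gaze_amplitude_deg,
    gaze_saturation_deg = gaze_saturation_deg,
    rotation_speed_deg_per_s = rotation_speed_deg_per_s,
    drift_onset_s = drift_onset_s,
    noise_spatial_corr = noise_spatial_corr,
    noise_sd = noise_sd,
    gaze_noise_sd = gaze_noise_sd,
    n_localizer_trials_per_orientation =
      as.integer(n_localizer_trials_per_orientation),
    confound_overlap = isTRUE(confound_overlap),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_subjects, cfg$n_trials_per_cell, cfg$n_blocks,
              cfg$n_sensors, cfg$n_localizer_trials_per_orientation)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    abort("all counts (subjects, trials, blocks, sensors) must be positive.")
  }
  gains <- c(cfg$neural_transient_gain, cfg$neural_sustained_gain,
             cfg$eye_dipole_gain, cfg$noise_sd, cfg$gaze_noise_sd)
  if (any(!is.finite(gains)) || any(gains < 0)) {
    abort("gains and noise levels must be finite and non-negative.")
  }
  if (cfg$noise_spatial_corr < 0 || cfg$noise_spatial_corr >= 1) {
    abort("`noise_spatial_corr` must lie in [0, 1).")
  }
  if (cfg$sample_rate_hz <= 0 || cfg$delay_s <= 0) {
    abort("`sample_rate_hz` and `delay_s` must be positive.")
  }
  invisible(cfg)
}

# Deterministic derived seeds: one stream per (subject, stage), kept inside
# 32-bit integer range. The master seed fully determines every stream.
derive_seed <- function(seed, subject, stream) {
  as.integer((abs(seed) + 104729 * subject + 7919 * stream) %% 2147483629L + 1L)
}

task_stimulus_orientations <- c(15, 75, 135)
localizer_orientations <- seq(15, 165, by = 30)

# Per-subject sensor mixing: A (neural orientation code, orthonormal columns)
# and G (eyeball-dipole coupling, frontal-weighted). With
# `confound_overlap = FALSE`, G is projected out of span(A) so the dipole
# artifact lives in a sensor subspace disjoint from the neural code.
subject_mixing <- function(n_sensors, subject_seed, confound_overlap) {
  withr::with_seed(subject_seed, {
    A <- qr.Q(qr(matrix(rnorm(n_sensors * 2), n_sensors, 2)))
    frontal <- exp(-(seq_len(n_sensors) - 1) / (n_sensors / 8))
    G <- frontal * matrix(rnorm(n_sensors * 2), n_sensors, 2)
    if (!confound_overlap) {
      G <- G - A %*% (t(A) %*% G)
    }
    G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
    axis_sign <- sample(c(-1, 1), 1)
    list(A = A, G = G, axis_sign = axis_sign)
  })
}

#' Orientation-tuned sensor pattern
#'
#' Stand-in for the cortical orientation code: a fixed random
#' `sensors x 2` mixing matrix `A` (orthonormal columns, drawn
#' deterministically from `subject_seed`) applied to the doubled-angle
#' coordinates, `pattern(a) = A %*% c(cos 2a, sin 2a)`. The pattern is smooth
#' and 180-degree periodic in orientation, and its norm is independent of
#' orientation because the columns of `A` are orthonormal.
#'
#' @param orientation orientation(s) in degrees, in \[0, 180).
#' @param sensors number of sensors.
#' @param subject_seed integer seed selecting the subject's mixing matrix.
#' @return a `sensors x length(orientation)` matrix of patterns.
#' @export
orientation_pattern <- function(orientation, sensors, subject_seed) {
  if (any(orientation < 0 | orientation >= 180)) {
    abort("`orientation` must lie in [0, 180).")
  }
  mix <- subject_mixing(sensors, subject_seed, confound_overlap = FALSE)
  rad <- orientation_to_doubled_rad(orientation)
  mix$A %*% rbind(cos(rad), sin(rad))
}

# Uniform time axis built on an integer sample grid to avoid rounding drift.
make_times <- function(tmin, tmax, fs) {
  seq.int(round(tmin * fs), round(tmax * fs)) / fs
}

# Transient stimulus-evoked envelope: alpha function peaking at ~0.12 s
# (the latency of the early visual evoked response), effectively decayed by
# ~0.6 s.
transient_envelope <- function(times, tau = 0.12) {
  env <- numeric(length(times))
  on <- times > 0
  env[on] <- (times[on] / tau) * exp(1 - times[on] / tau)
  env
}

# Sustained envelope: ramps 0.2..0.5 s, holds through the epoch.
sustained_envelope <- function(times) {
  pmin(pmax((times - 0.2) / 0.3, 0), 1)
}

# Spatially correlated sensor noise: C_ij = noise_sd^2 * r^|i-j|.
noise_chol <- function(n_sensors, r, noise_sd) {
  C <- noise_sd^2 * r^abs(outer(seq_len(n_sensors), seq_len(n_sensors), "-"))
  chol(C)
}

# Mental-orientation time course of one trial (degrees), and its gaze-tracked
# version clipped at the saturation angle.
mental_orientation <- function(times, stim, rotation, dir_sign, speed,
                               onset, saturation) {
  prog <- pmin(pmax((times - onset) * speed, 0), rotation)
  list(
    mental = wrap_orientation(stim + dir_sign * prog),
    tracked = wrap_orientation(stim + dir_sign * pmin(prog, saturation))
  )
}

subject_gaze_amplitudes <- function(cfg) {
  if (!is.null(cfg$gaze_amplitude_deg)) {
    rep_len(cfg$gaze_amplitude_deg, cfg$n_subjects)
  } else {
    withr::with_seed(derive_seed(cfg$seed, 0L, 9L),
                     rlnorm(cfg$n_subjects, meanlog = log(0.25), sdlog = 0.7))
  }
}

task_trial_table <- function(cfg, subject, subject_seed) {
  cells <- tidyr::expand_grid(
    rotation_deg = c(0, 60, 120, 180),
    direction = c("CW", "CCW"),
    rep = seq_len(cfg$n_trials_per_cell)
  )
  withr::with_seed(subject_seed, {
    blocks <- purrr::map(seq_len(cfg$n_blocks), function(b) {
      tab <- cells
      # balanced orientation assignment within each block: cycle a shuffled
      # orientation triplet across the replicates of every design cell
      tab$stimulus_orientation_deg <- as.vector(
        replicate(nrow(cells) / length(task_stimulus_orientations),
                  sample(task_stimulus_orientations))
      )
      tab <- tab[sample(nrow(tab)), ]
      tab$block <- b
      tab
    })
  })
  tab <- dplyr::bind_rows(blocks)
  sign <- ifelse(tab$direction == "CW", 1, -1)
  tibble::tibble(
    trial = seq_len(nrow(tab)),
    subject = subject,
    stimulus_orientation_deg = tab$stimulus_orientation_deg,
    rotation_deg = tab$rotation_deg,
    direction = tab$direction,
    target_orientation_deg = wrap_orientation(
      tab$stimulus_orientation_deg + sign * tab$rotation_deg),
    condition_label = paste0("rot", tab$rotation_deg),
    block = as.integer(tab$block)
  )
}

#' Generate synthetic working-memory / mental-rotation task data
#'
#' Simulates, per subject, the full combined working-memory (0 degrees) and
#' mental-rotation (60/120/180 degrees, CW/CCW) task: MEG-like sensor epochs,
#' gaze-position epochs and the generating ground truth. The gaze stays at
#' fixation until `drift_onset_s`, then drifts to a point at the subject's
#' amplitude along the current mental-orientation axis (orientation a maps to
#' screen position `amplitude * (sin a, cos a)`, with a per-subject choice of
#' axis end), tracks mental rotation at `rotation_speed_deg_per_s` but
#' saturates at `gaze_saturation_deg` from the start orientation, and holds
#' until the probe. The sensors receive (i) a transient orientation-tuned
#' neural pattern (0-0.5 s), (ii) optionally a sustained neural pattern of
#' the current mental orientation through the delay, (iii) the eyeball-dipole
#' artifact `eye_dipole_gain * G %*% gaze`, and (iv) spatially correlated
#' Gaussian noise (white in time).
#'
#' @param cfg a [generator_config()].
#' @return a list with elements `meg` and `gaze` (multi-subject
#'   [epoch_set()]s sharing one trial table) and `truth` (per-subject mixing
#'   matrices, amplitudes, axis signs, and the latent noise-free gaze
#'   trajectories).
#' @export
generate_task_data <- function(cfg) {
  validate_generator_config(cfg)
  fs <- cfg$sample_rate_hz
  times <- make_times(-1.1, 0.217 + cfg$delay_s, fs)
  nt <- length(times)
  amps <- subject_gaze_amplitudes(cfg)

  env_tr <- transient_envelope(times)
  env_sus <- sustained_envelope(times)
  ramp <- pmin(pmax((times - cfg$drift_onset_s) / 0.2, 0), 1)

  subjects <- purrr::map(seq_len(cfg$n_subjects), function(s) {
    seed_s <- derive_seed(cfg$seed, s, 1L)
    mix <- subject_mixing(cfg$n_sensors, derive_seed(cfg$seed, s, 0L),
                          cfg$confound_overlap)
    trials <- task_trial_table(cfg, s, seed_s)
    n <- nrow(trials)
    meg <- array(0, c(n, cfg$n_sensors, nt))
    gaze <- array(0, c(n, 2, nt))
    gaze_latent <- array(0, c(n, 2, nt))
    L <- noise_chol(cfg$n_sensors, cfg$noise_spatial_corr, cfg$noise_sd)
    withr::with_seed(derive_seed(cfg$seed, s, 2L), {
      for (k in seq_len(n)) {
        stim <- trials$stimulus_orientation_deg[k]
        dir_sign <- if (trials$direction[k] == "CW") 1 else -1
        ori <- mental_orientation(times, stim, trials$rotation_deg[k],
                                  dir_sign, cfg$rotation_speed_deg_per_s,
                                  cfg$drift_onset_s, cfg$gaze_saturation_deg)
        ax <- rbind(sin(ori$tracked * pi / 180), cos(ori$tracked * pi / 180))
        g_clean <- (amps[s] * mix$axis_sign) * sweep(ax, 2, ramp, "*")
        g_meas <- g_clean + cfg$gaze_noise_sd * matrix(rnorm(2 * nt), 2, nt)
        rad <- orientation_to_doubled_rad(ori$mental)
        neural <- cfg$neural_transient_gain *
          (mix$A %*% rbind(cos(rad[1]) * env_tr, sin(rad[1]) * env_tr))
        # note: transient pattern is locked to the *presented* orientation
        # (rad[1] == doubled stimulus angle at epoch start)
        if (cfg$neural_sustained_gain > 0) {
          neural <- neural + cfg$neural_sustained_gain *
            (mix$A %*% rbind(cos(rad) * env_sus, sin(rad) * env_sus))
        }
        noise <- t(L) %*% matrix(rnorm(cfg$n_sensors * nt), cfg$n_sensors, nt)
        meg[k, , ] <- neural + cfg$eye_dipole_gain * (mix$G %*% g_meas) + noise
        gaze[k, , ] <- g_meas
        gaze_latent[k, , ] <- g_clean
      }
    })
    list(trials = trials, meg = meg, gaze = gaze, gaze_latent = gaze_latent,
         mix = mix)
  })

  trials <- dplyr::bind_rows(purrr::map(subjects, "trials"))
  trials$trial <- seq_len(nrow(trials))
  meg <- epoch_set(
    do.call(abind3, purrr::map(subjects, "meg")), times,
    paste0("MEG", sprintf("%03d", seq_len(cfg$n_sensors))), trials)
  gaze <- epoch_set(
    do.call(abind3, purrr::map(subjects, "gaze")), times,
    c("gaze_x", "gaze_y"), trials)
  truth <- list(
    subjects = tibble::tibble(
      subject = seq_len(cfg$n_subjects),
      gaze_amplitude_deg = amps,
      axis_sign = purrr::map_dbl(subjects, ~ .x$mix$axis_sign)
    ),
    mixing = purrr::map(subjects, "mix"),
    gaze_latent = do.call(abind3, purrr::map(subjects, "gaze_latent"))
  )
  list(meg = meg, gaze = gaze, truth = truth)
}

#' Generate synthetic functional-localizer data
#'
#' Simulates the confound-free localizer: six orientations (15 to 165
#' degrees in steps of 30) presented 250 ms each while gaze remains at
#' fixation (measurement noise only). The sensors contain only the transient
#' orientation-tuned pattern plus noise, produced by the *same* per-subject
#' neural mixing matrix as [generate_task_data()] under the same master seed
#' — so decoders trained on the localizer generalize to genuine neural
#' signal in the task but, by construction, not to the eyeball-dipole
#' artifact (unless `confound_overlap = TRUE`).
#'
#' @param cfg a [generator_config()].
#' @return a list with elements `meg`, `gaze` and `truth`, as in
#'   [generate_task_data()].
#' @export
generate_localizer_data <- function(cfg) {
  validate_generator_config(cfg)
  fs <- cfg$sample_rate_hz
  times <- make_times(-0.2, 0.8, fs)
  nt <- length(times)
  env_tr <- transient_envelope(times)
  n_per <- cfg$n_localizer_trials_per_orientation

  subjects <- purrr::map(seq_len(cfg$n_subjects), function(s) {
    mix <- subject_mixing(cfg$n_sensors, derive_seed(cfg$seed, s, 0L),
                          cfg$confound_overlap)
    seed_s <- derive_seed(cfg$seed, s, 3L)
    withr::with_seed(seed_s, {
      oris <- sample(rep(localizer_orientations, n_per))
      n <- length(oris)
      trials <- tibble::tibble(
        trial = seq_len(n), subject = s,
        stimulus_orientation_deg = oris, rotation_deg = 0,
        direction = "CW", target_orientation_deg = oris,
        condition_label = "localizer",
        block = as.integer(ceiling(seq_len(n) / max(1, n %/% 6)))
      )
      meg <- array(0, c(n, cfg$n_sensors, nt))
      gaze <- array(0, c(n, 2, nt))
      L <- noise_chol(cfg$n_sensors, cfg$noise_spatial_corr, cfg$noise_sd)
      rad <- orientation_to_doubled_rad(oris)
      for (k in seq_len(n)) {
        neural <- cfg$neural_transient_gain *
          (mix$A %*% rbind(cos(rad[k]) * env_tr, sin(rad[k]) * env_tr))
        noise <- t(L) %*% matrix(rnorm(cfg$n_sensors * nt), cfg$n_sensors, nt)
        meg[k, , ] <- neural + noise
        gaze[k, , ] <- cfg$gaze_noise_sd * matrix(rnorm(2 * nt), 2, nt)
      }
      list(trials = trials, meg = meg, gaze = gaze, mix = mix)
    })
  })

  trials <- dplyr::bind_rows(purrr::map(subjects, "trials"))
  trials$trial <- seq_len(nrow(trials))
  meg <- epoch_set(
    do.call(abind3, purrr::map(subjects, "meg")), times,
    paste0("MEG", sprintf("%03d", seq_len(cfg$n_sensors))), trials)
  gaze <- epoch_set(
    do.call(abind3, purrr::map(subjects, "gaze")), times,
    c("gaze_x", "gaze_y"), trials)
  truth <- list(
    subjects = tibble::tibble(subject = seq_len(cfg$n_subjects)),
    mixing = purrr::map(subjects, "mix")
  )
  list(meg = meg, gaze = gaze, truth = truth)
}

# Bind 3-D arrays along the first (trial) dimension.
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(purrr::map_int(parts, ~ dim(.x)[1]))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
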