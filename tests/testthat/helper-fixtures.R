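# Shared fixtures: tiny epoch sets and trial tables built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

make_trials <- function(orientations, rotation = 0, direction = "CW",
                        block = 1L) {
  n <- length(orientations)
  rotation <- rep_len(rotation, n)
  direction <- rep_len(direction, n)
  sign <- ifelse(toupper(direction) == "CW", 1, -1)
  tibble::tibble(
    trial = seq_len(n),
    stimulus_orientation_deg = orientations,
    rotation_deg = rotation,
    direction = direction,
    target_orientation_deg = wrap_orientation(orientations + sign * rotation),
    condition_label = paste0("rot", rotation),
    block = rep_len(as.integer(block), n)
  )
}

make_epochs <- function(data, times = NULL, trials = NULL) {
  d <- dim(data)
  times <- times %||% ((seq_len(d[3]) - 1) / 100)
  trials <- trials %||%
    make_trials(rep_len(c(15, 75, 135), d[1]))
  epoch_set(data, times, paste0("f", seq_len(d[2])), trials)
}

# ground-truth world for the inverted encoding model: six orientations mixed
# into p sensors through an orthonormal doubled-angle code, plus (optionally
# spatially correlated) Gaussian noise
simulate_iem_world <- function(n = 240, p = 12, noise = 0.2, rho_n = 0,
                               seed = 1) {
  withr::with_seed(seed, {
    phi <- rep(seq(15, 165, 30), length.out = n)
    A <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
    rad <- orientation_to_doubled_rad(phi)
    S <- cbind(cos(rad), sin(rad)) %*% t(A)
    Cn <- rho_n^abs(outer(1:p, 1:p, "-"))
    E <- matrix(rnorm(n * p), n, p) %*% chol(Cn) * noise
    list(X = S + E, phi = phi, A = A)
  })
}

# small scaled generator configuration used across tests; any argument of
# generator_config() can be overridden
test_cfg <- function(...) {
  defaults <- list(
    n_subjects = 1, n_blocks = 3, n_sensors = 16, sample_rate_hz = 40,
    delay_s = 2, n_localizer_trials_per_orientation = 24, seed = 42
  )
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}
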