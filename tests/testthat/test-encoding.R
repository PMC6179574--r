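test_that("von Mises basis responses follow the closed form", {
  b <- encoding_basis(24, 5)
  expect_equal(b$centers_deg[2] - b$centers_deg[1], 7.5)
  C <- basis_responses(b, b$centers_deg)
  expect_equal(diag(C), rep(1, 24))  # peak 1 at each center
  # 90 degrees away: cos of the doubled difference is -1
  C90 <- basis_responses(b, wrap_orientation(b$centers_deg[1] + 90))
  expect_equal(C90[1, 1], exp(-2 * 5), tolerance = 1e-12)
  # 180-degree periodicity in orientation
  expect_equal(basis_responses(b, 10), basis_responses(b, 10 + 180 - 180))
  # equally spaced basis: row sums identical across orientations
  rs <- rowSums(basis_responses(b, runif(50, 0, 180)))
  expect_lt(diff(range(rs)), 1e-9)
  expect_error(basis_responses(b, 190), "\\[0, 180\\)")
})

test_that("noiseless decoding recovers the generating orientation", {
  w <- simulate_iem_world(noise = 1e-6, seed = 2)
  m <- fit_encoding_model(w$X, w$phi, lambda = 0.5)
  dec <- decode_orientation(m, w$X)
  expect_lt(max(orientation_distance(dec$theta_deg, w$phi)), 1)
  # channel profile peaks at the channel nearest the true orientation
  k <- which.max(dec$channels[1, ])
  expect_lt(orientation_distance(m$basis$centers_deg[k], w$phi[1]), 8)
})

test_that("with lambda = 1 (spherical noise) filters align with patterns", {
  w <- simulate_iem_world(noise = 0.3, seed = 3)
  m <- fit_encoding_model(w$X, w$phi, lambda = 1)
  # w_j = p_j / (p_j' p_j) * (1/nu cancels in the unit-gain normalization)
  for (j in c(1, 7, 19)) {
    expect_equal(as.vector(m$filters[j, ]),
                 as.vector(m$patterns[, j] / sum(m$patterns[, j]^2)),
                 tolerance = 1e-10)
  }
})

test_that("degenerate channel activities are handled", {
  w <- simulate_iem_world(seed = 4)
  m <- fit_encoding_model(w$X, w$phi)
  # one-hot channel activity -> the channel's center
  J <- m$basis$n_channels
  th <- oculomem:::resultant_orientation(diag(J)[5, , drop = FALSE] * 2,
                                         m$basis$centers_deg)
  expect_equal(th$theta_deg, m$basis$centers_deg[5])
  # equal activity in all channels -> zero resultant, flagged
  th0 <- oculomem:::resultant_orientation(matrix(1, 1, J),
                                          m$basis$centers_deg)
  expect_true(is.na(th0$theta_deg))
  expect_equal(th0$n_undefined, 1)
  expect_error(fit_encoding_model(w$X[w$phi == 15, ], w$phi[w$phi == 15]),
               "rank-deficient")
})

test_that("rho equals the mean-cosine oracle and is antisymmetric", {
  set.seed(5)
  theta <- runif(300, 0, 180)
  phi <- runif(300, 0, 180)
  oracle <- mean(cos(2 * (theta - phi) * pi / 180))
  expect_equal(rho(theta, phi), oracle, tolerance = 1e-12)
  expect_equal(rho(wrap_orientation(phi + 90), phi), -1)
  expect_equal(rho(theta, wrap_orientation(phi + 90)),
               -rho(theta, phi), tolerance = 1e-12)
  expect_true(abs(rho(theta, phi)) <= 1)
  expect_error(rho(theta, phi[1:5]), "equal length")
  expect_message(rho(c(15, NA), c(15, 20)), "dropping")
})

test_that("decoding error decreases monotonically with SNR", {
  rmse <- sapply(c(0.2, 0.6, 1.8), function(noise) {
    w <- simulate_iem_world(noise = noise, seed = 6)
    m <- fit_encoding_model(w$X[1:180, ], w$phi[1:180])
    dec <- decode_orientation(m, w$X[181:240, ])
    circular_rmse(dec$theta_deg, w$phi[181:240])
  })
  expect_true(all(diff(rmse) > 0))
})

test_that("noise-covariance-aware filters beat identity filters", {
  set.seed(7)
  wins <- replicate(30, {
    sd_seed <- sample.int(1e6, 1)
    w <- simulate_iem_world(noise = 0.8, rho_n = 0.8, seed = sd_seed)
    tr <- 1:180; te <- 181:240
    m <- fit_encoding_model(w$X[tr, ], w$phi[tr], lambda = 0.05)
    m_id <- m
    m_id$filters <- t(m$patterns) / colSums(m$patterns^2)
    d1 <- decode_orientation(m, w$X[te, ])
    d2 <- decode_orientation(m_id, w$X[te, ])
    circular_rmse(d2$theta_deg, w$phi[te]) -
      circular_rmse(d1$theta_deg, w$phi[te])
  })
  expect_gt(mean(wins > 0), 0.8)
  expect_gt(mean(wins), 0)
})

test_that("localizer-trained decoding scores rho against 45-degree-rotated truth at zero", {
  cfg <- test_cfg(neural_transient_gain = 1.5, eye_dipole_gain = 0,
                  gaze_amplitude_deg = 0)
  loc <- generate_localizer_data(cfg)
  locm <- smooth_moving_average(baseline_correct(loc$meg), 0.1)
  cv <- crossval_localizer_rho(locm, lambda = 0.05, seed = 2)
  peak <- which.max(cv$rho)
  expect_gt(cv$rho[peak], 0.5)
  expect_true(cv$time[peak] > 0 & cv$time[peak] < 0.5)
  # same decode scored against truth rotated 45 degrees -> orthogonal, ~0
  m <- fit_encoding_model(locm$data[, , peak],
                          locm$trials$stimulus_orientation_deg)
  dec <- decode_orientation(m, locm$data[, , peak])
  expect_equal(
    rho(dec$theta_deg,
        wrap_orientation(locm$trials$stimulus_orientation_deg + 45)),
    0, tolerance = 0.1)
})
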