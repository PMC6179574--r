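#' Von Mises orientation channel basis
#'
#' A bank of hypothetical orientation channels with tuning curves
#' `exp(kappa * (cos(delta) - 1))` in doubled-angle space (peak-normalized
#' to 1 at the channel center), centered at equally spaced orientations.
#' Because orientation is periodic over 180 degrees, all circular arithmetic
#' is done on doubled angles (see [orientation_to_doubled_rad()]).
#'
#' @param n_channels number of channels (default 24).
#' @param kappa von Mises concentration parameter (default 5).
#' @return an object of class `encoding_basis` with orientation-space
#'   channel centers in degrees.
#' @export
encoding_basis <- function(n_channels = 24, kappa = 5) {
  if (n_channels < 2) abort("need at least 2 channels.")
  structure(
    list(
      n_channels = as.integer(n_channels),
      centers_deg = seq(0, 180, length.out = n_channels + 1)[seq_len(n_channels)],
      kappa = kappa
    ),
    class = "encoding_basis"
  )
}

#' Channel responses of the von Mises basis
#'
#' Design matrix of predicted channel activities:
#' `C[t, j] = exp(kappa * (cos(2*phi_t - 2*mu_j) - 1))` with angles in
#' radians after doubling. The response is 1 when the orientation sits at
#' the channel center and `exp(-2*kappa)` at 90 degrees away (cos of the
#' doubled difference = -1), and is 180-degree periodic in orientation.
#'
#' @param basis an [encoding_basis()].
#' @param orientations orientations in degrees, in \[0, 180).
#' @return a `length(orientations) x n_channels` matrix.
#' @export
basis_responses <- function(basis, orientations) {
  if (any(orientations < 0 | orientations >= 180)) {
    abort("`orientations` must lie in [0, 180).")
  }
  d <- outer(orientation_to_doubled_rad(orientations),
             orientation_to_doubled_rad(basis$centers_deg), "-")
  exp(basis$kappa * (cos(d) - 1))
}

#' Fit the inverted encoding model
#'
#' Estimates, at one time point, the sensor pattern of each orientation
#' channel and a noise-covariance-aware spatial filter to invert the forward
#' model. Each channel's pattern is estimated *independently* by univariate
#' least squares of the data onto that channel's predicted activity
#' (`p_j = X' c_j / (c_j' c_j)`), which is what allows more channels than
#' there are distinct stimulus orientations. The noise covariance `Sigma` is
#' taken from the residuals of the full forward prediction and
#' shrinkage-regularized towards `nu * I`. The inverse model uses unit-gain,
#' noise-suppressing filters `w_j = Sigma^-1 p_j / (p_j' Sigma^-1 p_j)`,
#' which reduce to plain pattern projection when `Sigma` is proportional to
#' the identity.
#'
#' Because the tuning curves of neighboring channels overlap, the
#' independently estimated patterns equal the true generating patterns
#' convolved with a symmetric kernel on the (doubled) circle; this blurs the
#' reconstructed channel profile but leaves the circular-mean orientation
#' estimate unbiased.
#'
#' @param X numeric matrix, trials x features.
#' @param orientations presented orientation per trial, degrees.
#' @param basis an [encoding_basis()].
#' @param lambda shrinkage strength for the noise covariance.
#' @return an object of class `encoding_model`.
#' @export
fit_encoding_model <- function(X, orientations, basis = encoding_basis(),
                               lambda = 0.05) {
  X <- as.matrix(X)
  if (nrow(X) != length(orientations)) {
    abort("`orientations` must have one entry per row of `X`.")
  }
  C <- basis_responses(basis, orientations)
  if (qr(C)$rank < 3) {
    abort(paste0("design is rank-deficient: need trials spanning more ",
                 "distinct orientations."))
  }
  tab <- table(orientations)
  if (any(tab < 2)) {
    warn("some orientations have fewer than 2 trials; estimates may be unstable.")
  }
  # independent per-channel pattern estimation
  P <- crossprod(X, C) %*% diag(1 / colSums(C^2), basis$n_channels)
  R <- X - C %*% t(P)
  Sigma_raw <- crossprod(R) / (nrow(X) - 1)
  nu <- mean(diag(Sigma_raw))
  Sigma <- (1 - lambda) * Sigma_raw + lambda * nu * diag(ncol(X))
  SiP <- solve(Sigma, P)
  W <- t(SiP) / colSums(P * SiP)  # rows: unit-gain filters w_j
  structure(
    list(basis = basis, patterns = P, sigma = Sigma, filters = W,
         lambda = lambda, nu = nu),
    class = "encoding_model"
  )
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf(
    "<encoding_model> %d von Mises channels (kappa = %g), %d features, lambda = %g\n",
    x$basis$n_channels, x$basis$kappa, nrow(x$patterns), x$lambda))
  invisible(x)
}

#' Tidy a fitted encoding model
#'
#' One row per (channel, feature) with the channel center, estimated sensor
#' pattern and spatial filter weight.
#'
#' @param x an `encoding_model`.
#' @param ... unused.
#' @export
tidy.encoding_model <- function(x, ...) {
  J <- x$basis$n_channels
  p <- nrow(x$patterns)
  tibble::tibble(
    channel = rep(seq_len(J), each = p),
    center_deg = rep(x$basis$centers_deg, each = p),
    feature = rep(seq_len(p), times = J),
    pattern = as.vector(x$patterns),
    filter = as.vector(t(x$filters))
  )
}

#' @rdname tidy.encoding_model
#' @export
glance.encoding_model <- function(x, ...) {
  tibble::tibble(
    n_channels = x$basis$n_channels,
    kappa = x$basis$kappa,
    n_features = nrow(x$patterns),
    lambda = x$lambda,
    nu = x$nu
  )
}

#' Decode orientation from sensor data
#'
#' Applies the inverse model to obtain channel activities `c = W x` and
#' collapses them to a single orientation estimate: the circular mean of the
#' channel centers weighted by their activities,
#' `theta = arg(sum_j c_j exp(i * mu_j))` in doubled-angle space, mapped
#' back to \[0, 180). Trials whose resultant vector is (numerically) zero
#' have no defined orientation; they are returned as `NA` with a reported
#' count, and are skipped by [rho()].
#'
#' @param model an [fit_encoding_model()] result.
#' @param x a feature vector or a trials x features matrix.
#' @return a list with `channels` (trials x channels), `theta_deg`
#'   (decoded orientations, `NA` where undefined) and `n_undefined`.
#' @export
decode_orientation <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$filters)) {
    abort(sprintf("`x` has %d features but the model expects %d.",
                  ncol(x), ncol(model$filters)))
  }
  ch <- x %*% t(model$filters)
  res <- resultant_orientation(ch, model$basis$centers_deg)
  if (res$n_undefined > 0) {
    rlang::inform(sprintf(
      "%d trial(s) had a zero resultant vector; decoded orientation undefined.",
      res$n_undefined))
  }
  list(channels = ch, theta_deg = res$theta_deg,
       n_undefined = res$n_undefined)
}

# Channel activities -> circular-mean orientation (degrees), NA when the
# resultant vector vanishes.
resultant_orientation <- function(ch, centers_deg) {
  mu <- orientation_to_doubled_rad(centers_deg)
  zr <- ch %*% cos(mu)
  zi <- ch %*% sin(mu)
  mod <- sqrt(zr^2 + zi^2)
  scale <- rowSums(abs(ch)) + .Machine$double.eps
  undef <- mod / scale < 1e-12
  theta <- doubled_rad_to_orientation(atan2(zi, zr))
  theta[undef] <- NA_real_
  list(theta_deg = as.vector(theta), n_undefined = sum(undef))
}

#' Circular association between decoded and true orientations
#'
#' The V-test statistic for circular uniformity with a prespecified
#' direction, computed on doubled angles: with
#' `z = 1/N * sum_k exp(i * (2*theta_k - 2*phi_k))` (radians),
#' `rho = |z| * cos(arg z) = Re(z)`, i.e. the mean cosine of the doubled
#' angular error. It behaves like a correlation coefficient: +1 when
#' decoded and true orientations agree exactly, -1 when they are 90 degrees
#' apart (counterphase after doubling), and 0 when they are unrelated or
#' systematically 45 degrees apart (orthogonal after doubling).
#'
#' `NA` decoded orientations (undefined resultants) are dropped with a
#' message.
#'
#' @param theta decoded orientations, degrees.
#' @param phi true orientations, degrees.
#' @return scalar in \[-1, 1\].
#' @export
rho <- function(theta, phi) {
  if (length(theta) != length(phi)) {
    abort("`theta` and `phi` must have equal length.")
  }
  keep <- !is.na(theta) & !is.na(phi)
  if (sum(keep) == 0) abort("no trials with defined decoded orientation.")
  if (any(!keep)) {
    rlang::inform(sprintf("dropping %d trial(s) with undefined orientation.",
                          sum(!keep)))
  }
  mean(cos(orientation_to_doubled_rad(theta[keep] - phi[keep])))
}

#' Localizer-to-task generalization of the orientation decoder
#'
#' Fits the encoding model at every localizer time point (on all localizer
#' trials) and decodes every task trial at every task time point, scoring
#' each (train, test) cell with [rho()] between decoded and true
#' orientations, split by rotation condition. Because rho is a mean over
#' trials, condition-wise values can be pooled by an `n`-weighted average.
#'
#' Multi-subject inputs (matching `subject` columns in both epoch sets) are
#' split internally and gain a `subject` column.
#'
#' @param localizer localizer [epoch_set()] (training data).
#' @param task task [epoch_set()] (test data); must share the feature space.
#' @param basis an [encoding_basis()].
#' @param lambda noise-covariance shrinkage.
#' @param relative_to score decoding against the `"presented"` stimulus
#'   orientation or the rotation `"target"` orientation.
#' @return a tibble of class `tg_tbl` with `train_time`, `test_time`,
#'   `rotation_deg`, `rho`, `n_trials` (plus `subject`); attribute
#'   `chance = 0`.
#' @export
localizer_generalization <- function(localizer, task,
                                     basis = encoding_basis(),
                                     lambda = 0.05,
                                     relative_to = c("presented", "target")) {
  relative_to <- match.arg(relative_to)
  if (!identical(localizer$feature_labels, task$feature_labels)) {
    abort("localizer and task epochs must share the same feature space.")
  }
  subjects <- unique(localizer$trials[["subject"]] %||% 1L)
  if (length(subjects) > 1) {
    out <- purrr::map(subjects, function(s) {
      dplyr::mutate(
        localizer_generalization(
          subset_trials(localizer, localizer$trials$subject == s),
          subset_trials(task, task$trials$subject == s),
          basis = basis, lambda = lambda, relative_to = relative_to),
        subject = s, .before = 1)
    })
    res <- dplyr::bind_rows(out)
    attributes(res)[c("chance", "measure")] <-
      attributes(out[[1]])[c("chance", "measure")]
    class(res) <- class(out[[1]])
    return(res)
  }

  phi <- switch(relative_to,
                presented = task$trials$stimulus_orientation_deg,
                target = task$trials$target_orientation_deg)
  rot <- task$trials$rotation_deg
  rots <- sort(unique(rot))
  n <- n_trials(task)
  nt_task <- length(task$times)
  nt_loc <- length(localizer$times)
  Mflat <- matrix(aperm(task$data, c(1, 3, 2)), n * nt_task,
                  dim(task$data)[2])
  phi_rep <- rep(phi, times = nt_task)
  mu <- orientation_to_doubled_rad(basis$centers_deg)
  # group (rotation x test time) mean of cos(2 theta - 2 phi)
  gid <- (match(rep(rot, times = nt_task), rots) - 1L) * nt_task +
    rep(seq_len(nt_task), each = n)
  acc <- matrix(0, nt_loc, length(rots) * nt_task)
  for (t in seq_len(nt_loc)) {
    mod <- fit_encoding_model(localizer$data[, , t],
                              localizer$trials$stimulus_orientation_deg,
                              basis, lambda)
    ch <- Mflat %*% t(mod$filters)
    theta <- resultant_orientation(ch, basis$centers_deg)$theta_deg
    err <- cos(orientation_to_doubled_rad(theta - phi_rep))
    err[is.na(err)] <- 0  # undefined decodes contribute no association
    acc[t, ] <- rowsum(err, gid)[, 1]
  }
  cnt <- tabulate(match(rot, rots), nbins = length(rots))
  res <- array(acc, c(nt_loc, nt_task, length(rots)))
  res <- sweep(res, 3, cnt, "/")
  out <- tibble::tibble(
    train_time = rep(localizer$times, times = nt_task * length(rots)),
    test_time = rep(rep(task$times, each = nt_loc), times = length(rots)),
    rotation_deg = rep(rots, each = nt_loc * nt_task),
    rho = as.vector(res),
    n_trials = rep(cnt, each = nt_loc * nt_task)
  )
  structure(out, chance = 0, measure = "rho",
            class = c("tg_tbl", class(out)))
}

#' Cross-validated orientation decoding within the localizer
#'
#' Sanity check of the encoding decoder on its own training task: k-fold
#' cross-validated [rho()] at matched train/test time points.
#'
#' @param e localizer [epoch_set()] (single subject).
#' @param basis an [encoding_basis()].
#' @param lambda noise-covariance shrinkage.
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @return a tibble with `time`, `rho`, `n_trials`.
#' @export
crossval_localizer_rho <- function(e, basis = encoding_basis(),
                                   lambda = 0.05, folds = 8, seed = 1L) {
  phi <- e$trials$stimulus_orientation_deg
  n <- n_trials(e)
  nt <- length(e$times)
  classes <- sort(unique(phi))
  fold_id <- integer(n)
  withr::with_seed(seed, {
    for (k in seq_along(classes)) {
      idx <- sample(which(phi == classes[k]))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  err_sum <- numeric(nt)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    for (t in seq_len(nt)) {
      mod <- fit_encoding_model(e$data[!te, , t], phi[!te], basis, lambda)
      ch <- e$data[te, , t] %*% t(mod$filters)
      theta <- resultant_orientation(ch, basis$centers_deg)$theta_deg
      errs <- cos(orientation_to_doubled_rad(theta - phi[te]))
      err_sum[t] <- err_sum[t] + sum(errs, na.rm = TRUE)
    }
  }
  tibble::tibble(time = e$times, rho = err_sum / n, n_trials = n)
}
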