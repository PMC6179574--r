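#' Weighted up/down adaptive staircase
#'
#' The probe-jitter staircase used to equalize task difficulty: the jitter
#' starts at 15 degrees, increases by 1 degree after an incorrect response
#' and decreases by 0.5488 degrees after two *consecutive* correct
#' responses (the consecutive-correct counter resets after every decrement
#' and every error). The asymmetric steps drive performance towards the
#' equilibrium where up- and down-steps balance,
#' `1 * (1 - p^2) = 0.5488 * p^2`, i.e. `p = sqrt(1 / 1.5488) ~ 0.8036` —
#' a theoretical target of about 80% correct. The jitter is floored at
#' `floor_deg` so a perfect observer cannot drive it negative.
#'
#' @param start starting jitter, degrees.
#' @param step_up increment after an incorrect response, degrees.
#' @param step_down decrement after two consecutive correct responses,
#'   degrees.
#' @param floor_deg smallest allowed jitter, degrees.
#' @return an object of class `staircase_state`.
#' @export
staircase_state <- function(start = 15, step_up = 1, step_down = 0.5488,
                            floor_deg = 0.1) {
  if (start <= 0) abort("`start` must be positive.")
  structure(
    list(jitter = start, step_up = step_up, step_down = step_down,
         floor = floor_deg, consecutive_correct = 0L),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("<staircase_state> jitter = %.4f deg (streak %d)\n",
              x$jitter, x$consecutive_correct))
  invisible(x)
}

#' Advance the staircase by one response
#'
#' @param s a [staircase_state()].
#' @param correct logical, was the response correct?
#' @return the updated `staircase_state`.
#' @export
staircase_update <- function(s, correct) {
  if (isTRUE(correct)) {
    s$consecutive_correct <- s$consecutive_correct + 1L
    if (s$consecutive_correct == 2L) {
      s$jitter <- max(s$jitter - s$step_down, s$floor)
      s$consecutive_correct <- 0L
    }
  } else {
    s$jitter <- s$jitter + s$step_up
    s$consecutive_correct <- 0L
  }
  s
}

#' Cumulative-Gaussian psychometric observer
#'
#' Factory for a monotone psychometric function
#' `p(jitter) = 0.5 + (0.5 - lapse) * pnorm(jitter, threshold, slope)`,
#' ranging over (0.5, 1): at zero jitter the clockwise/counterclockwise
#' judgment is at guessing level, and large jitters approach (near-)perfect
#' performance.
#'
#' @param threshold jitter of the psychometric midpoint, degrees.
#' @param slope Gaussian slope parameter, degrees.
#' @param lapse lapse rate subtracted from the upper asymptote.
#' @return a function of jitter returning p(correct).
#' @export
psychometric_cgauss <- function(threshold = 8, slope = 4, lapse = 0.02) {
  function(jitter) 0.5 + (0.5 - lapse) * pnorm(jitter, threshold, slope)
}

#' Simulate an observer driven by the staircase
#'
#' Runs the staircase against a stochastic observer whose probability of a
#' correct response is `psychometric(current jitter)`, and reports the
#' proportion correct over the post-burn-in half of the trials (where the
#' staircase has converged to its equilibrium jitter).
#'
#' @param psychometric a monotone increasing function jitter -> p(correct)
#'   with range within (0.5, 1), e.g. [psychometric_cgauss()].
#' @param n_trials number of simulated trials.
#' @param seed RNG seed.
#' @param state starting [staircase_state()].
#' @return a list with `prop_correct` (asymptotic proportion correct over
#'   the final half), `trace` (tibble: `trial`, `jitter`, `p_correct`,
#'   `correct`) and `final_jitter`.
#' @export
simulate_observer <- function(psychometric, n_trials = 2000, seed = 1L,
                              state = staircase_state()) {
  if (n_trials < 2) abort("`n_trials` must be at least 2.")
  p_lo <- psychometric(state$floor)
  p_hi <- psychometric(state$jitter + 50)
  if (abs(p_hi - p_lo) < 1e-6) {
    warn("psychometric function appears constant; staircase will not converge.")
  }
  jitter <- numeric(n_trials)
  pcor <- numeric(n_trials)
  correct <- logical(n_trials)
  withr::with_seed(seed, {
    s <- state
    for (i in seq_len(n_trials)) {
      jitter[i] <- s$jitter
      pcor[i] <- psychometric(s$jitter)
      correct[i] <- runif(1) < pcor[i]
      s <- staircase_update(s, correct[i])
    }
  })
  burn <- seq_len(floor(n_trials / 2))
  list(
    prop_correct = mean(correct[-burn]),
    trace = tibble::tibble(trial = seq_len(n_trials), jitter = jitter,
                           p_correct = pcor, correct = correct),
    final_jitter = jitter[n_trials]
  )
}

#' Staircase equilibrium performance (pair approximation)
#'
#' Closed-form target performance of the weighted up/down rule: at
#' equilibrium the expected jitter drift vanishes,
#' `step_up * (1 - p^2) = step_down * p^2`, giving
#' `p = sqrt(step_up / (step_up + step_down))`. For the default steps this
#' is approximately 0.8036.
#'
#' @param step_up,step_down staircase step sizes.
#' @return the equilibrium probability correct.
#' @export
staircase_equilibrium_p <- function(step_up = 1, step_down = 0.5488) {
  sqrt(step_up / (step_up + step_down))
}
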