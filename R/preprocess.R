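#' Baseline-correct epochs
#'
#' Subtracts, per trial and feature, the mean over a baseline window. MEG
#' epochs are conventionally baselined on -200 to 0 ms relative to stimulus
#' onset; gaze epochs on -200 to 0 ms relative to *cue* onset (the cue
#' precedes the stimulus by 0.834 s), which removes slow drifts in the
#' eye-tracker signal.
#'
#' The window is interpreted on closed interval samples (`t0 <= t <= t1`)
#' relative to the chosen reference event.
#'
#' @param e an [epoch_set()].
#' @param window length-2 numeric, baseline window in seconds relative to
#'   `reference_event`.
#' @param reference_event `"stimulus"` (time 0 of the epoch) or `"cue"`.
#' @param cue_onset_s cue onset relative to stimulus onset, seconds.
#' @return a baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(e, window = c(-0.2, 0),
                             reference_event = c("stimulus", "cue"),
                             cue_onset_s = -0.834) {
  reference_event <- match.arg(reference_event)
  offset <- if (reference_event == "cue") cue_onset_s else 0
  win <- sort(window) + offset
  sel <- e$times >= win[1] - 1e-9 & e$times <= win[2] + 1e-9
  if (!any(sel)) {
    abort(sprintf("baseline window [%.3f, %.3f] s contains no samples of the epoch.",
                  win[1], win[2]))
  }
  base <- apply(e$data[, , sel, drop = FALSE], c(1, 2), mean)
  e$data <- e$data - array(base, dim(e$data))
  e
}

#' Temporal smoothing with a centered moving average
#'
#' Boxcar-averages each trial and feature over time with a centered window
#' (default 100 ms). Near the epoch edges the window is truncated
#' (shrinking towards the boundary), which avoids both missing values and
#' phase shifts. The operation is linear and leaves the trial and feature
#' dimensions untouched.
#'
#' @param e an [epoch_set()].
#' @param window_s window length in seconds; must be at least one sample
#'   interval.
#' @return a smoothed `epoch_set`.
#' @export
smooth_moving_average <- function(e, window_s = 0.1) {
  if (!is.numeric(window_s) || window_s <= 0) {
    abort("`window_s` must be positive.")
  }
  dt <- mean(diff(e$times))
  if (window_s < dt - 1e-12) {
    abort("`window_s` is shorter than one sample interval.")
  }
  half <- floor(window_s / dt / 2)
  if (half == 0) return(e)
  nt <- length(e$times)
  d <- dim(e$data)
  # cumulative-sum implementation on the flattened (trial*feature) x time view
  x <- matrix(e$data, d[1] * d[2], d[3])
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  lo <- pmax(seq_len(nt) - half, 1)
  hi <- pmin(seq_len(nt) + half, nt)
  sm <- (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1, each = nrow(x))
  e$data <- array(sm, d)
  e
}
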