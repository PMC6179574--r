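#' Epoched multichannel data container
#'
#' An `epoch_set` bundles a 3-D numeric array of epoched data
#' (`trial x feature x time`) with its time axis, feature labels and a
#' per-trial metadata table. Features are MEG sensors (arbitrary consistent
#' units) or gaze coordinates (degrees visual angle; x rightward, y upward,
#' from screen center). Time is in seconds relative to stimulus onset; in the
#' working-memory task the cue appears at -0.834 s (417 ms cue + 417 ms blank
#' before the grating).
#'
#' The trial table is a tibble with one row per trial and (at least) the
#' columns `trial`, `stimulus_orientation_deg`, `rotation_deg`, `direction`
#' (`"CW"`/`"CCW"`; lower/mixed case is normalized to upper case),
#' `target_orientation_deg`, `condition_label` and `block`. Orientations are
#' degrees clockwise from vertical in \[0, 180); the target orientation must
#' equal `(stimulus + rotation) mod 180` for clockwise rotations and
#' `(stimulus - rotation) mod 180` for counterclockwise ones. A `subject`
#' column is added by the multi-subject generators.
#'
#' @param data numeric 3-D array, `trial x feature x time`.
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing with a uniform step.
#' @param feature_labels character vector naming the features.
#' @param trials data frame of per-trial metadata (coerced to a tibble).
#' @return an object of class `epoch_set`.
#' @examples
#' tr <- tibble::tibble(
#'   trial = 1:2, stimulus_orientation_deg = c(15, 75), rotation_deg = 0,
#'   direction = "CW", target_orientation_deg = c(15, 75),
#'   condition_label = "rot0", block = 1L
#' )
#' e <- epoch_set(array(rnorm(2 * 3 * 4), c(2, 3, 4)),
#'                times = seq(0, 0.3, by = 0.1),
#'                feature_labels = c("s1", "s2", "s3"), trials = tr)
#' e
#' @export
epoch_set <- function(data, times, feature_labels, trials) {
  trials <- validate_trial_table(trials)
  e <- structure(
    list(
      data = data,
      times = as.numeric(times),
      feature_labels = as.character(feature_labels),
      trials = trials
    ),
    class = "epoch_set"
  )
  validate_epoch_set(e)
}

#' Validate an epoch_set's invariants
#'
#' Checks dimension agreement, a strictly increasing uniform time axis, and
#' absence of non-finite values. Called by [epoch_set()] and [read_epochs()].
#'
#' @param e an `epoch_set`.
#' @return `e`, invisibly unchanged, or an error naming the violated field.
#' @export
validate_epoch_set <- function(e) {
  if (!is.array(e$data) || length(dim(e$data)) != 3L) {
    abort("`data` must be a 3-D array [trial, feature, time].")
  }
  d <- dim(e$data)
  if (d[1] != nrow(e$trials)) {
    abort(sprintf("`data` has %d trials but `trials` has %d rows.",
                  d[1], nrow(e$trials)))
  }
  if (d[2] != length(e$feature_labels)) {
    abort(sprintf("`data` has %d features but %d feature labels were given.",
                  d[2], length(e$feature_labels)))
  }
  if (d[3] != length(e$times)) {
    abort(sprintf("`data` has %d time points but `times` has length %d.",
                  d[3], length(e$times)))
  }
  if (length(e$times) > 1) {
    dt <- diff(e$times)
    if (any(dt <= 0)) abort("`times` must be strictly increasing.")
    if (diff(range(dt)) > 1e-6 * mean(dt)) {
      abort("`times` must have a uniform sampling step.")
    }
  }
  if (anyNA(e$data) || any(!is.finite(e$data))) {
    abort("`data` contains NA or non-finite values.")
  }
  invisible(e)
}

trial_table_columns <- c(
  "trial", "stimulus_orientation_deg", "rotation_deg", "direction",
  "target_orientation_deg", "condition_label", "block"
)

#' Validate and normalize a trial metadata table
#'
#' Enforces the column set, orientation ranges, the allowed rotation amounts,
#' and the consistency rule `target = (stimulus +/- rotation) mod 180` (sign
#' by rotation direction). `direction` is normalized to upper case `"CW"` /
#' `"CCW"`; any other value is rejected.
#'
#' @param trials a data frame of per-trial metadata.
#' @return the validated trial table as a tibble.
#' @export
validate_trial_table <- function(trials) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(trial_table_columns, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  trials$direction <- toupper(as.character(trials$direction))
  bad_dir <- !trials$direction %in% c("CW", "CCW")
  if (any(bad_dir)) {
    abort(sprintf("invalid `direction` value(s): %s (must be CW or CCW)",
                  paste(unique(trials$direction[bad_dir]), collapse = ", ")))
  }
  for (col in c("stimulus_orientation_deg", "target_orientation_deg")) {
    v <- trials[[col]]
    if (any(!is.finite(v)) || any(v < 0 | v >= 180)) {
      abort(sprintf("`%s` must lie in [0, 180).", col))
    }
  }
  if (any(!trials$rotation_deg %in% c(0, 60, 120, 180))) {
    abort("`rotation_deg` must be one of 0, 60, 120, 180.")
  }
  sign <- ifelse(trials$direction == "CW", 1, -1)
  expected <- wrap_orientation(
    trials$stimulus_orientation_deg + sign * trials$rotation_deg
  )
  if (any(orientation_distance(expected, trials$target_orientation_deg) > 1e-9)) {
    abort("`target_orientation_deg` inconsistent with stimulus/rotation/direction.")
  }
  trials
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d features x %d samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  time: %.3f .. %.3f s (fs = %.6g Hz)\n",
              x$times[1], x$times[length(x$times)],
              1 / mean(diff(x$times))))
  cat(sprintf("  features: %s%s\n",
              paste(head(x$feature_labels, 4), collapse = ", "),
              if (d[2] > 4) ", ..." else ""))
  if ("subject" %in% names(x$trials)) {
    cat(sprintf("  subjects: %d\n", dplyr::n_distinct(x$trials$subject)))
  }
  invisible(x)
}

#' Number of trials in an epoch_set
#' @param e an `epoch_set`.
#' @export
n_trials <- function(e) dim(e$data)[1]

#' Subset an epoch_set by trial
#'
#' @param e an `epoch_set`.
#' @param idx integer or logical trial index.
#' @return an `epoch_set` with the selected trials.
#' @export
subset_trials <- function(e, idx) {
  epoch_set(e$data[idx, , , drop = FALSE], e$times, e$feature_labels,
            e$trials[idx, , drop = FALSE])
}

#' Convert an epoch_set to a long tibble
#'
#' One row per (trial, feature, time); convenient for ggplot2 but large, so
#' intended for small selections.
#'
#' @param x an `epoch_set`.
#' @param ... unused.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(x$trials$trial, times = d[2] * d[3]),
    feature = rep(rep(x$feature_labels, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' Write an epoch_set to disk
#'
#' The data block, time axis and feature labels are stored in a single
#' self-describing RDS container at `<path>.epochs.rds`; the trial table is
#' written alongside as a tab-delimited UTF-8 TSV (`<path>.trials.tsv`) with a
#' fixed column order, so the metadata stay human-readable and tool-friendly.
#' The round trip through [read_epochs()] is bit-exact for the data and exact
#' for all metadata.
#'
#' @param e an `epoch_set`.
#' @param path file path prefix (without extension).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(e, path) {
  validate_epoch_set(e)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("directory does not exist: %s", dir))
  }
  saveRDS(
    list(data = e$data, times = e$times, feature_labels = e$feature_labels),
    paste0(path, ".epochs.rds")
  )
  extra <- setdiff(names(e$trials), trial_table_columns)
  readr::write_tsv(
    e$trials[, c(trial_table_columns[1], extra,
                 trial_table_columns[-1])],
    paste0(path, ".trials.tsv")
  )
  invisible(path)
}

#' Read an epoch_set from disk
#'
#' Counterpart of [write_epochs()]. All `epoch_set` and trial-table
#' invariants are re-validated on read, so a corrupted or hand-edited file
#' fails with an error naming the offending field.
#'
#' @param path file path prefix used in [write_epochs()].
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path) {
  arr_file <- paste0(path, ".epochs.rds")
  tsv_file <- paste0(path, ".trials.tsv")
  for (f in c(arr_file, tsv_file)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  arr <- readRDS(arr_file)
  trials <- readr::read_tsv(tsv_file, show_col_types = FALSE,
                            progress = FALSE)
  epoch_set(arr$data, arr$times, arr$feature_labels, trials)
}
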