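#' Cross-validated temporal generalization of the probabilistic classifier
#'
#' Trains the Gaussian probabilistic classifier at every time point on
#' pooled trials from all rotation conditions (stratified, seeded k-fold
#' cross-validation) and evaluates the class posteriors of held-out trials
#' at every time point, yielding a train-time x test-time generalization
#' surface of the mean posterior probability.
#'
#' When the epochs carry the task design (default; `labels = NULL` uses
#' `stimulus_orientation_deg`), posteriors are aggregated by rotation
#' condition and by the *relative* class offset
#' `(class - stimulus) * direction mod 180` (0, 60 or 120 degrees), so the
#' same result table answers all of: decoding of the presented stimulus per
#' condition, decoding of the rotation target, and the rise of intermediate
#' orientations during mental rotation. With explicit `labels` the function
#' returns the plain mean true-class posterior instead.
#'
#' Multi-subject epoch sets are split internally and the result gains a
#' `subject` column.
#'
#' @param e an [epoch_set()].
#' @param labels optional explicit class labels (one per trial); disables
#'   the condition/offset breakdown.
#' @param folds number of cross-validation folds.
#' @param lambda shrinkage strength passed to [fit_classifier()].
#' @param seed seed for the stratified fold assignment.
#' @return a tibble of class `tg_tbl` with columns `train_time`,
#'   `test_time`, `posterior`, `n_trials`, plus `rotation_deg` and
#'   `rel_offset_deg` in design mode and `subject` for multi-subject input.
#'   Attributes: `chance` (1 / number of classes) and `measure`.
#' @export
crossval_temporal_generalization <- function(e, labels = NULL, folds = 8,
                                             lambda = 0.05, seed = 1L) {
  if (folds < 2) abort("`folds` must be at least 2.")
  subjects <- unique(e$trials[["subject"]] %||% 1L)
  if (length(subjects) > 1) {
    out <- purrr::map(subjects, function(s) {
      sel <- e$trials$subject == s
      tg <- crossval_temporal_generalization(
        subset_trials(e, sel),
        labels = if (!is.null(labels)) labels[sel] else NULL,
        folds = folds, lambda = lambda,
        seed = derive_seed(seed, match(s, subjects), 4L))
      dplyr::mutate(tg, subject = s, .before = 1)
    })
    res <- dplyr::bind_rows(out)
    attributes(res)[c("chance", "measure")] <-
      attributes(out[[1]])[c("chance", "measure")]
    class(res) <- class(out[[1]])
    return(res)
  }

  design_mode <- is.null(labels)
  if (design_mode) labels <- e$trials$stimulus_orientation_deg
  classes <- sort(unique(labels))
  K <- length(classes)
  y <- match(labels, classes)
  n <- n_trials(e)
  nt <- length(e$times)
  if (min(table(y)) < folds) {
    abort("every class needs at least `folds` trials.")
  }

  # group id per (trial, class): in design mode, rotation x relative offset;
  # otherwise the true class only (NA entries are dropped from aggregation)
  if (design_mode) {
    dir_sign <- ifelse(e$trials$direction == "CW", 1, -1)
    rel <- sapply(classes, function(cl) {
      wrap_orientation(dir_sign * (cl - e$trials$stimulus_orientation_deg))
    })
    key <- paste(e$trials$rotation_deg, round(rel))
    levs <- sort(unique(as.vector(key)))
    gmat <- matrix(match(key, levs), n, K)
    parts <- do.call(rbind, strsplit(levs, " "))
    group_levels <- tibble::tibble(
      g = seq_along(levs),
      rotation_deg = as.numeric(parts[, 1]),
      rel_offset_deg = as.numeric(parts[, 2])
    )
  } else {
    gmat <- matrix(NA_integer_, n, K)
    gmat[cbind(seq_len(n), y)] <- 1L
    group_levels <- tibble::tibble(g = 1L)
  }
  G <- nrow(group_levels)

  fold_id <- integer(n)
  withr::with_seed(seed, {
    for (k in seq_len(K)) {
      idx <- sample(which(y == k))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })

  # flattened (trial, time) x feature view for fast evaluation
  Mflat <- matrix(aperm(e$data, c(1, 3, 2)), n * nt, dim(e$data)[2])

  acc <- matrix(0, nt, G * nt)
  for (f in seq_len(folds)) {
    idx_te <- which(fold_id == f)
    idx_tr <- which(fold_id != f)
    n_te <- length(idx_te)
    rows <- rep(idx_te, times = nt) + rep((seq_len(nt) - 1) * n, each = n_te)
    M_te <- Mflat[rows, , drop = FALSE]
    trial_rep <- rep(idx_te, times = nt)
    time_rep <- rep(seq_len(nt), each = n_te)
    cid <- as.vector(sapply(seq_len(K), function(k) {
      (gmat[trial_rep, k] - 1L) * nt + time_rep
    }))
    ok <- !is.na(cid)
    cid_ok <- cid[ok]
    for (t in seq_len(nt)) {
      mod <- fit_classifier(e$data[idx_tr, , t, drop = FALSE][, , 1],
                            labels[idx_tr], lambda)
      a <- M_te %*% mod$weights +
        matrix(mod$offsets, nrow(M_te), K, byrow = TRUE)
      P <- softmax_rows(a)
      s <- rowsum(as.vector(P)[ok], cid_ok)
      acc[t, as.integer(rownames(s))] <-
        acc[t, as.integer(rownames(s))] + s[, 1]
    }
  }

  gcount <- tabulate(gmat[!is.na(gmat)], nbins = G)
  res <- array(acc, c(nt, nt, G))
  res <- sweep(res, 3, gcount, "/")
  out <- tibble::tibble(
    train_time = rep(e$times, times = nt * G),
    test_time = rep(rep(e$times, each = nt), times = G),
    g = rep(group_levels$g, each = nt * nt),
    posterior = as.vector(res)
  )
  out <- dplyr::left_join(
    out, dplyr::mutate(group_levels, n_trials = gcount), by = "g")
  out$g <- NULL
  structure(out, chance = 1 / K, measure = "posterior",
            class = c("tg_tbl", class(out)))
}

#' Condition-wise decoding profiles from a generalization surface
#'
#' Averages a temporal generalization table over a fixed training window
#' (rows), producing per-condition decoding time courses — e.g. the
#' sustained working-memory trace versus the declining mental-rotation
#' traces for a 0.5-1.5 s training window. `target` selects which
#' class-relative posterior is reported: the class of the *presented*
#' stimulus, the class of the rotation *target* (identical to the presented
#' class for 0- and 180-degree rotations), a fixed relative `"offset"` in
#' degrees, or `"all"` offsets.
#'
#' @param tg a `tg_tbl` from [crossval_temporal_generalization()], in design
#'   mode (with `rotation_deg` / `rel_offset_deg` columns).
#' @param train_window length-2 numeric, training-time window in seconds.
#' @param target `"presented"`, `"target"`, `"offset"` or `"all"`.
#' @param offset_deg relative offset in degrees when `target = "offset"`.
#' @return a tibble with `test_time`, `posterior`, the grouping columns and
#'   the same `chance` attribute as `tg`.
#' @export
condition_profiles <- function(tg, train_window,
                               target = c("presented", "target", "offset",
                                          "all"),
                               offset_deg = NULL) {
  target <- match.arg(target)
  measure <- attr(tg, "measure") %||%
    if ("posterior" %in% names(tg)) "posterior" else "rho"
  win <- sort(train_window)
  keep <- tg$train_time >= win[1] - 1e-9 & tg$train_time <= win[2] + 1e-9
  if (!any(keep)) abort("`train_window` contains no training time points.")
  tg <- tg[keep, ]
  by_design <- "rel_offset_deg" %in% names(tg)
  if (!by_design && !target %in% c("presented", "all")) {
    abort("class-relative targets require a classifier generalization table.")
  }
  grp <- intersect(c("subject", "rotation_deg", "rel_offset_deg",
                     "test_time"), names(tg))
  out <- dplyr::summarise(
    dplyr::group_by(tg, dplyr::across(dplyr::all_of(grp))),
    "{measure}" := mean(.data[[measure]]),
    n_trials = .data$n_trials[1],
    .groups = "drop"
  )
  if (by_design) {
    out <- switch(
      target,
      presented = dplyr::filter(out, .data$rel_offset_deg == 0),
      target = dplyr::filter(
        out, .data$rel_offset_deg == wrap_orientation(.data$rotation_deg)),
      offset = {
        if (is.null(offset_deg)) abort("`offset_deg` required for target = 'offset'.")
        dplyr::filter(out, .data$rel_offset_deg == wrap_orientation(offset_deg))
      },
      all = out
    )
  }
  structure(out, chance = attr(tg, "chance"), measure = attr(tg, "measure"))
}

#' Class-specific spatial patterns (difference ERFs)
#'
#' For each class, the difference between the class-mean evoked field and
#' the grand-mean evoked field across all trials, averaged over a time
#' window. With balanced classes the per-feature patterns sum to zero across
#' classes. Useful to inspect *what* a decoder picks up — e.g. whether the
#' informative topography sits on frontal (ocular) or posterior sensors.
#'
#' @param e an [epoch_set()] (single- or multi-subject).
#' @param labels class labels; defaults to `stimulus_orientation_deg`.
#' @param time_window length-2 numeric window in seconds.
#' @return a tibble with `feature`, `class`, `pattern` (and `subject` for
#'   multi-subject input).
#' @export
spatial_pattern <- function(e, labels = NULL, time_window) {
  subjects <- unique(e$trials[["subject"]] %||% 1L)
  if (length(subjects) > 1) {
    return(dplyr::bind_rows(purrr::map(subjects, function(s) {
      sel <- e$trials$subject == s
      dplyr::mutate(
        spatial_pattern(subset_trials(e, sel),
                        labels = if (!is.null(labels)) labels[sel] else NULL,
                        time_window = time_window),
        subject = s, .before = 1)
    })))
  }
  if (is.null(labels)) labels <- e$trials$stimulus_orientation_deg
  win <- sort(time_window)
  sel <- e$times >= win[1] - 1e-9 & e$times <= win[2] + 1e-9
  if (!any(sel)) abort("`time_window` contains no samples.")
  erf <- apply(e$data[, , sel, drop = FALSE], c(1, 2), mean)
  classes <- sort(unique(labels))
  if (length(unique(table(labels))) > 1) {
    warn("classes are unbalanced; patterns will not sum to zero across classes.")
  }
  grand <- colMeans(erf)
  pats <- purrr::map(classes, function(cl) {
    tibble::tibble(
      feature = e$feature_labels,
      class = as.character(cl),
      pattern = colMeans(erf[labels == cl, , drop = FALSE]) - grand
    )
  })
  dplyr::bind_rows(pats)
}
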