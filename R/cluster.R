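#' Cluster-based sign-flip permutation test
#'
#' Tests subject-level decoding maps (1-D time courses or 2-D temporal
#' generalization matrices) against a chance level with cluster-based
#' correction for multiple comparisons. Per point, a two-tailed one-sample
#' t test against `chance` defines supra-threshold points (`p < threshold_p`);
#' clusters are formed by adjacency (chain adjacency in 1-D, 4-connectivity
#' in 2-D), separately for positive and negative t values, and scored by
#' their summed t mass. The null distribution is built by randomly
#' sign-flipping each subject's centered map (`map - chance`) with
#' probability 1/2 and collecting, per permutation, the largest positive and
#' most negative cluster masses. Cluster p values use the add-one rule
#' `p = (1 + #{permutation mass >= observed}) / (1 + n_perm)`, so the
#' smallest attainable p is `1 / (1 + n_perm)`. Positive and negative
#' clusters are each compared at `threshold_p`.
#'
#' @param maps subject-level maps: a `subjects x points` matrix (1-D) or a
#'   `subjects x rows x cols` array (2-D). At least 2 subjects.
#' @param chance chance level to test against (e.g. 1/3 for three-class
#'   posteriors, 0 for rho).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the sign flips.
#' @param threshold_p two-tailed point-wise threshold defining clusters, and
#'   the significance level for cluster p values.
#' @return an object of class `cluster_test`: observed t map, a tibble of
#'   clusters (`id`, `sign`, `mass`, `p_value`, `significant`, `mask`
#'   list-column), and the permutation null distributions.
#' @export
cluster_permutation_test <- function(maps, chance = 0, n_perm = 1000,
                                     seed = 1L, threshold_p = 0.05) {
  if (is.data.frame(maps)) {
    abort("`maps` must be a subjects x points matrix or subjects x rows x cols array.")
  }
  dims <- dim(maps)
  if (is.null(dims) || length(dims) < 2 || length(dims) > 3) {
    abort("`maps` must be a 2-D matrix or 3-D array with subjects first.")
  }
  n_sub <- dims[1]
  if (n_sub < 2) abort("need at least 2 subjects (t test undefined).")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  map_dim <- dims[-1]
  X <- matrix(maps, n_sub) - chance  # subjects x points, centered
  npts <- ncol(X)
  tcrit <- qt(1 - threshold_p / 2, df = n_sub - 1)

  # one-sample t for arbitrary sign assignments, vectorized over
  # permutations: sum(x^2) is sign-invariant, so only the mean changes
  ss <- colSums(X^2)
  t_for_signs <- function(S) {
    m <- S %*% X / n_sub
    v <- (rep(ss, each = nrow(S)) - n_sub * m^2) / (n_sub - 1)
    v[v < 0] <- 0
    m / sqrt(v / n_sub)
  }

  t_obs <- as.vector(t_for_signs(matrix(1, 1, n_sub)))
  obs <- find_clusters(t_obs, tcrit, map_dim)

  null_pos <- numeric(n_perm)
  null_neg <- numeric(n_perm)
  withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                    n_perm, n_sub)
  })
  chunk <- max(1L, floor(5e6 / npts))
  for (start in seq(1, n_perm, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_perm)
    Tp <- t_for_signs(signs[idx, , drop = FALSE])
    for (j in seq_along(idx)) {
      mm <- max_cluster_masses(Tp[j, ], tcrit, map_dim)
      null_pos[idx[j]] <- mm[1]
      null_neg[idx[j]] <- mm[2]
    }
  }

  clusters <- obs$clusters
  if (nrow(clusters) > 0) {
    clusters$p_value <- purrr::map2_dbl(
      clusters$mass, clusters$sign,
      function(mass, sign) {
        if (sign > 0) (1 + sum(null_pos >= mass)) / (1 + n_perm)
        else (1 + sum(null_neg <= mass)) / (1 + n_perm)
      })
    clusters$significant <- clusters$p_value < threshold_p
  } else {
    clusters$p_value <- numeric(0)
    clusters$significant <- logical(0)
  }

  structure(
    list(
      t_observed = array(t_obs, map_dim),
      map_dim = map_dim,
      chance = chance,
      clusters = clusters,
      threshold_p = threshold_p,
      t_critical = tcrit,
      n_perm = n_perm,
      n_subjects = n_sub,
      null_positive = null_pos,
      null_negative = null_neg
    ),
    class = "cluster_test"
  )
}

# Connected components of supra-threshold points, sign-separated.
# 1-D: runs of consecutive supra-threshold points of equal sign.
# 2-D: 4-connectivity via igraph components.
find_clusters <- function(tvec, tcrit, map_dim) {
  lab <- integer(length(tvec))
  state <- integer(length(tvec))
  state[tvec > tcrit] <- 1L
  state[tvec < -tcrit] <- -1L
  if (length(map_dim) == 1) {
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    next_id <- 0L
    for (i in seq_along(r$values)) {
      if (r$values[i] != 0L) {
        next_id <- next_id + 1L
        lab[starts[i]:ends[i]] <- next_id
      }
    }
  } else {
    lab <- label_components_2d(state, map_dim)
  }
  ids <- setdiff(unique(lab), 0L)
  clusters <- tibble::tibble(
    id = seq_along(ids),
    sign = purrr::map_dbl(ids, ~ sign(tvec[lab == .x][1])),
    mass = purrr::map_dbl(ids, ~ sum(tvec[lab == .x])),
    mask = purrr::map(ids, ~ array(lab == .x, map_dim))
  )
  clusters <- clusters[order(-abs(clusters$mass)), ]
  clusters$id <- seq_len(nrow(clusters))
  list(clusters = clusters, labels = array(lab, map_dim))
}

label_components_2d <- function(state, map_dim) {
  M <- matrix(state, map_dim[1], map_dim[2])
  on <- which(M != 0L)
  lab <- integer(length(state))
  if (length(on) == 0) return(lab)
  nr <- map_dim[1]
  # vertical neighbors (same column, adjacent rows)
  i <- on[(on %% nr) != 0L]
  v_ok <- i[M[i + 1L] == M[i]]
  # horizontal neighbors (same row, adjacent columns)
  j <- on[on <= (map_dim[2] - 1L) * nr]
  h_ok <- j[M[j + nr] == M[j]]
  edges <- cbind(c(v_ok, h_ok), c(v_ok + 1L, h_ok + nr))
  vid <- match(seq_along(state), on)
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(cbind(vid[edges[, 1]], vid[edges[, 2]])))
  }
  comp <- igraph::components(g)$membership
  lab[on] <- comp
  lab
}

# Largest positive and most negative cluster mass of a t map (0 if none).
max_cluster_masses <- function(tvec, tcrit, map_dim) {
  state <- integer(length(tvec))
  state[tvec > tcrit] <- 1L
  state[tvec < -tcrit] <- -1L
  if (!any(state != 0L)) return(c(0, 0))
  if (length(map_dim) == 1) {
    r <- rle(state)
    ends <- cumsum(r$lengths)
    masses <- purrr::map_dbl(which(r$values != 0L), function(i) {
      sum(tvec[(ends[i] - r$lengths[i] + 1):ends[i]])
    })
  } else {
    lab <- label_components_2d(state, map_dim)
    masses <- rowsum(tvec[lab != 0L], lab[lab != 0L])[, 1]
  }
  c(max(c(masses[masses > 0], 0)), min(c(masses[masses < 0], 0)))
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test> %d subjects, %s map, chance = %g, %d permutations\n",
    x$n_subjects, paste(x$map_dim, collapse = " x "), x$chance, x$n_perm))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(tidy(x))
  }
  invisible(x)
}

#' Tidy a cluster test result
#'
#' One row per cluster with sign, summed-t mass, extent and p value.
#'
#' @param x a `cluster_test`.
#' @param ... unused.
#' @export
tidy.cluster_test <- function(x, ...) {
  dplyr::mutate(
    x$clusters[, c("id", "sign", "mass", "p_value", "significant")],
    n_points = purrr::map_int(x$clusters$mask, sum)
  )
}

#' @rdname tidy.cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_perm = x$n_perm,
    threshold_p = x$threshold_p,
    chance = x$chance,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_
  )
}

#' Cluster test of a horizontal cross-section of generalization surfaces
#'
#' Averages each subject's generalization surface over a fixed training
#' window (rows), then runs the 1-D cluster permutation test on the
#' resulting per-subject test-time profiles. This is the standard way to ask
#' whether decoding trained in a given window (e.g. 0.5-1.5 s) is above
#' chance across the delay.
#'
#' @param tg a multi-subject `tg_tbl` (with a `subject` column) from
#'   [crossval_temporal_generalization()] or [localizer_generalization()],
#'   or a tibble with columns `subject`, `train_time`, `test_time` and a
#'   value column.
#' @param train_window length-2 numeric training window in seconds.
#' @param chance chance level; defaults to the table's `chance` attribute.
#' @param value name of the value column (default: the table's measure).
#' @param rotation restrict to one rotation condition (degrees), if the
#'   table has a `rotation_deg` column; `NULL` pools conditions weighted by
#'   trial counts.
#' @param ... passed to [cluster_permutation_test()] (`n_perm`, `seed`,
#'   `threshold_p`).
#' @return a `cluster_test`; its `map_dim` spans the test times, stored in
#'   the `times` element.
#' @export
test_crosssection <- function(tg, train_window, chance = NULL, value = NULL,
                              rotation = NULL, ...) {
  if (!"subject" %in% names(tg)) {
    abort("`tg` must contain a `subject` column (one surface per subject).")
  }
  value <- value %||% attr(tg, "measure") %||% "posterior"
  chance <- chance %||% attr(tg, "chance")
  if (is.null(chance)) abort("`chance` must be supplied.")
  win <- sort(train_window)
  tg <- dplyr::filter(tg, .data$train_time >= win[1] - 1e-9,
                      .data$train_time <= win[2] + 1e-9)
  if (nrow(tg) == 0) abort("`train_window` contains no training time points.")
  if (!is.null(rotation)) {
    if (!"rotation_deg" %in% names(tg)) {
      abort("`tg` has no `rotation_deg` column to filter on.")
    }
    tg <- dplyr::filter(tg, .data$rotation_deg == rotation)
    if (nrow(tg) == 0) abort(sprintf("unknown rotation condition: %s", rotation))
  }
  if ("rel_offset_deg" %in% names(tg)) {
    tg <- dplyr::filter(tg, .data$rel_offset_deg == 0)
  }
  tg$..w <- if ("n_trials" %in% names(tg)) tg$n_trials else 1
  prof <- dplyr::summarise(
    dplyr::group_by(tg, .data$subject, .data$test_time),
    value = sum(.data[[value]] * .data$..w) / sum(.data$..w),
    .groups = "drop"
  )
  prof <- dplyr::arrange(prof, .data$subject, .data$test_time)
  wide <- tidyr::pivot_wider(prof, names_from = "test_time",
                             values_from = "value")
  times <- as.numeric(names(wide)[-1])
  maps <- as.matrix(wide[, -1])
  res <- cluster_permutation_test(maps, chance = chance, ...)
  res$times <- times
  res
}
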