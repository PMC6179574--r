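#' Plot a temporal generalization surface
#'
#' Raster of train time x test time decoding performance, faceted by
#' rotation condition when present. For classifier tables the presented-
#' stimulus posterior (`rel_offset_deg == 0`) is shown; multi-subject
#' tables are averaged across subjects.
#'
#' @param object a `tg_tbl` from [crossval_temporal_generalization()] or
#'   [localizer_generalization()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tg_tbl <- function(object, ...) {
  measure <- attr(object, "measure") %||% "posterior"
  chance <- attr(object, "chance") %||% 0
  df <- tibble::as_tibble(object)
  if ("rel_offset_deg" %in% names(df)) {
    df <- dplyr::filter(df, .data$rel_offset_deg == 0)
  }
  grp <- intersect(c("train_time", "test_time", "rotation_deg"), names(df))
  df <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
    value = mean(.data[[measure]]), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$test_time, .data$train_time,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = chance, low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  name = measure) +
    ggplot2::labs(x = "test time (s)", y = "train time (s)") +
    ggplot2::theme_minimal()
  if ("rotation_deg" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~rotation_deg,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot condition-wise decoding profiles
#'
#' Time courses of decoding performance per rotation condition (and
#' relative class offset, if present), averaged across subjects, with a
#' dashed chance line.
#'
#' @param profiles a tibble from [condition_profiles()].
#' @return a ggplot object.
#' @export
plot_condition_profiles <- function(profiles) {
  chance <- attr(profiles, "chance") %||% 0
  df <- tibble::as_tibble(profiles)
  grp <- intersect(c("test_time", "rotation_deg", "rel_offset_deg"),
                   names(df))
  df <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
    posterior = mean(.data$posterior), .groups = "drop")
  aes <- if ("rel_offset_deg" %in% names(df)) {
    ggplot2::aes(.data$test_time, .data$posterior,
                 colour = factor(.data$rel_offset_deg))
  } else {
    ggplot2::aes(.data$test_time, .data$posterior)
  }
  p <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "test time (s)", y = "posterior probability",
                  colour = "offset (deg)") +
    ggplot2::theme_minimal()
  if ("rotation_deg" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~rotation_deg,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot a cluster permutation test
#'
#' 1-D tests: the observed t course with supra-threshold clusters shaded
#' (significant clusters in a stronger tone). 2-D tests: the t map with
#' significant clusters outlined by tiles.
#'
#' @param object a `cluster_test`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cluster_test <- function(object, ...) {
  if (length(object$map_dim) == 1) {
    x <- object$times %||% seq_len(object$map_dim)
    df <- tibble::tibble(x = x, t = as.vector(object$t_observed))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$t)) +
      ggplot2::geom_hline(yintercept = c(-1, 1) * object$t_critical,
                          linetype = "dotted", colour = "grey50") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "test time (s)", y = "t value") +
      ggplot2::theme_minimal()
    if (nrow(object$clusters)) {
      shade <- dplyr::bind_rows(purrr::pmap(
        object$clusters[, c("id", "mask", "significant")],
        function(id, mask, significant) {
          tibble::tibble(x = x[as.vector(mask)], id = id,
                         significant = significant)
        }))
      p <- p + ggplot2::geom_rug(
        data = shade,
        ggplot2::aes(x = .data$x, colour = .data$significant),
        inherit.aes = FALSE, sides = "b") +
        ggplot2::scale_colour_manual(
          values = c(`TRUE` = "#b2182b", `FALSE` = "grey65"),
          name = "significant")
    }
    p
  } else {
    df <- tibble::tibble(
      row = rep(seq_len(object$map_dim[1]), times = object$map_dim[2]),
      col = rep(seq_len(object$map_dim[2]), each = object$map_dim[1]),
      t = as.vector(object$t_observed)
    )
    sig <- object$clusters[object$clusters$significant, , drop = FALSE]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                          fill = .data$t)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b") +
      ggplot2::labs(x = "test time (index)", y = "train time (index)") +
      ggplot2::theme_minimal()
    if (nrow(sig)) {
      outline <- dplyr::bind_rows(purrr::map2(
        sig$mask, sig$id,
        function(m, id) dplyr::mutate(df[as.vector(m), c("row", "col")],
                                      id = id)))
      p <- p + ggplot2::geom_tile(
        data = outline,
        ggplot2::aes(.data$col, .data$row), fill = NA,
        colour = "black", linewidth = 0.1, inherit.aes = FALSE)
    }
    p
  }
}

#' Plot the gaze-position scatter summary
#'
#' Per-subject mean gaze positions in the analysis window, coloured by
#' stimulus orientation, with the orientation axes drawn through fixation —
#' the fingerprint of gaze drifting along the remembered grating's
#' orientation axis.
#'
#' @param scatter tibble from [run_full()]'s `gaze_scatter` element
#'   (columns `subject`, `stimulus_orientation_deg`, `gaze_x`, `gaze_y`).
#' @return a ggplot object.
#' @export
plot_gaze_scatter <- function(scatter) {
  r <- max(abs(c(scatter$gaze_x, scatter$gaze_y))) * 1.1
  axes <- dplyr::bind_rows(purrr::map(
    unique(scatter$stimulus_orientation_deg), function(o) {
      tibble::tibble(
        stimulus_orientation_deg = o,
        x = c(-r, r) * sin(o * pi / 180), y = c(-r, r) * cos(o * pi / 180))
    }))
  ggplot2::ggplot(scatter,
                  ggplot2::aes(.data$gaze_x, .data$gaze_y,
                               colour = factor(.data$stimulus_orientation_deg))) +
    ggplot2::geom_line(data = axes, ggplot2::aes(.data$x, .data$y,
                                                 colour = factor(.data$stimulus_orientation_deg)),
                       alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "gaze x (deg)", y = "gaze y (deg)",
                  colour = "orientation (deg)") +
    ggplot2::theme_minimal()
}
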