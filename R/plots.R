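#' Plot a direction tuning curve
#'
#' Mean evoked response per stimulus direction with rep-to-rep SD bars and
#' a dashed line at the spontaneous rate.
#'
#' @param object a [build_tuning_curve()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot tuning_curve
#' @export
autoplot.tuning_curve <- function(object, ...) {
  sa <- attr(object, "sa")
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$direction_deg, y = .data$mean_response)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_response - .data$sd_response,
        ymax = .data$mean_response + .data$sd_response
      ),
      width = 5, colour = "grey55"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_hline(yintercept = sa, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, 90)) +
    ggplot2::labs(
      x = "motion direction (deg)", y = "evoked rate (spikes/s)",
      caption = sprintf("spontaneous activity %.2f spikes/s", sa)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted double-Gaussian tuning curve
#'
#' The measured curve with the fitted model evaluated on a fine direction
#' grid, annotated with the fitting error.
#'
#' @param object a [fit_double_gaussian()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dg_fit
#' @export
autoplot.dg_fit <- function(object, ...) {
  p <- autoplot.tuning_curve(object$curve)
  if (is.na(object$mse)) {
    return(p + ggplot2::labs(subtitle = "degenerate fit (not accepted)"))
  }
  grid <- tibble(direction_deg = seq(0, 360, by = 2))
  grid$fitted <- predict(object, grid$direction_deg)
  p +
    ggplot2::geom_line(
      data = grid,
      ggplot2::aes(x = .data$direction_deg, y = .data$fitted),
      colour = "#c23b22", linewidth = 0.7
    ) +
    ggplot2::labs(subtitle = sprintf(
      "fitting error %.4f (%s)", object$mse,
      if (object$accepted) "accepted" else "rejected"
    ))
}

#' Grouped bar chart of binned metric distributions
#'
#' The percentage of neurons per bin and group for one metric of a study
#' report (or any [bin_distribution()]-shaped table with a `group`
#' column).
#'
#' @param bins a tibble with columns `group`, `metric`, `bin`, `percent`.
#' @param metric which metric to plot (default: all, facetted).
#' @return a ggplot object.
#' @export
plot_bin_distribution <- function(bins, metric = NULL) {
  if (!is.null(metric)) {
    bins <- dplyr::filter(bins, .data$metric %in% !!metric)
  }
  ggplot2::ggplot(
    bins,
    ggplot2::aes(x = .data$bin, y = .data$percent, fill = .data$group)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of neurons", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_bin_distribution
#' @param object a `study_report`.
#' @param ... passed to `plot_bin_distribution()`.
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  plot_bin_distribution(object$bins, ...)
}
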