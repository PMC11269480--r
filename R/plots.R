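#' Plot the enzymatic investment plane
#'
#' Scatter of the per-sample investment proportions `x = C/(C+P)` versus
#' `y = C/(C+N)`, coloured by limitation class, with the equal-investment
#' diagonal. Points above the diagonal have more N- than P-relative
#' investment (angle < 45, N limitation); points below it indicate P
#' limitation.
#'
#' @param object A [limitation_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enzlim_vectors
#' @export
autoplot.enzlim_vectors <- function(object, ...) {
  d <- tibble::as_tibble(object)[!is.na(object$angle_deg), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::scale_colour_manual(
      values = c(N_LIMITED = "#1f78b4", BALANCED = "grey50",
                 P_LIMITED = "#e3211c"),
      drop = FALSE
    ) +
    ggplot2::labs(
      x = "C vs P investment  x = C/(C+P)",
      y = "C vs N investment  y = C/(C+N)",
      colour = "Limitation"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.enzlim_vectors
#' @param vectors A [limitation_table()] result.
#' @export
plot_investment <- function(vectors, ...) autoplot(vectors, ...)

#' Plot a driver correlation screen
#'
#' Dot plot of Pearson correlations from [correlate_drivers()] (one panel
#' per response if a `response` column is present), highlighting
#' correlations with `p < 0.05`.
#'
#' @param correlations A tibble from [correlate_drivers()], optionally with
#'   a `response` column as produced by [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_driver_correlations <- function(correlations) {
  d <- dplyr::mutate(correlations,
                     significant = !is.na(.data$p_value) & .data$p_value < 0.05)
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$r,
                    y = stats::reorder(.data$predictor, .data$r),
                    colour = .data$significant)
  ) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#e3211c",
                                            `FALSE` = "grey55")) +
    ggplot2::labs(x = "Pearson r", y = NULL, colour = "p < 0.05") +
    ggplot2::theme_minimal()
  if ("response" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~response)
  }
  p
}

#' Plot permutation importances
#'
#' Bar chart of relative contributions (% of summed mean-MSE increase) from
#' [permutation_importance()].
#'
#' @param importance A tibble from [permutation_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(
    importance,
    ggplot2::aes(x = .data$importance_pct,
                 y = stats::reorder(.data$term, .data$importance_pct))
  ) +
    ggplot2::geom_col(fill = "#66452c", width = 0.7) +
    ggplot2::labs(x = "Relative contribution (%)", y = NULL) +
    ggplot2::theme_minimal()
}
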