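#' Plot a predictor-vs-ROR scatter with its regression line
#'
#' Reproduces the standard affinity-versus-reporting-odds figure: one point
#' per drug, the least-squares line in red, and the pointwise 95%
#' confidence band in grey.
#'
#' @param object A `dili_scatter` from [export_scatter()].
#' @param label_drugs Add drug-name labels to the points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dili_scatter
#' @export
autoplot.dili_scatter <- function(object, label_drugs = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$ror)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "red", linewidth = 0.8) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = attr(object, "predictor"),
      y = "Reporting odds ratio",
      title = sprintf("%s vs ROR (%s stratum)",
                      attr(object, "predictor"), attr(object, "stratum")),
      subtitle = sprintf("r = %.2f, n = %d", attr(object, "r"), attr(object, "n"))
    ) +
    ggplot2::theme_minimal()
  if (label_drugs) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$drug),
                                vjust = -0.7, size = 3)
  }
  p
}

#' Forest-style plot of disproportionality results
#'
#' ROR point estimates with 95% Wald intervals per drug, faceted by
#' stratum, on a log scale with the null line at 1; signals are
#' highlighted.
#'
#' @param object A `dili_disprop` from [run_disproportionality()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dili_disprop
#' @export
autoplot.dili_disprop <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(.data$is_reported, !is.na(.data$ror))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ror,
                                  y = stats::reorder(.data$drug, .data$ror),
                                  colour = .data$is_signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ror_low,
                                          xmax = .data$ror_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                 name = "signal") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Reporting odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of the correlation battery
#'
#' Pearson r per predictor and stratum; significant tests (uncorrected
#' p < 0.05) are filled.
#'
#' @param object A `dili_battery` from [run_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dili_battery
#' @export
autoplot.dili_battery <- function(object, ...) {
  d <- tibble::as_tibble(object) |> dplyr::filter(!is.na(.data$r))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r,
                                  y = stats::reorder(.data$predictor, .data$r),
                                  shape = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "p < 0.05") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Pearson r (ROR vs predictor)", y = NULL) +
    ggplot2::theme_minimal()
}
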