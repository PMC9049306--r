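#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot lifetime prevalence by payer
#'
#' @param prevalence Output of [lifetime_prevalence()].
#' @param targets Optional target table from [prevalence_targets()] to
#'   overlay as points.
#' @return A ggplot.
#' @export
plot_prevalence <- function(prevalence, targets = NULL) {
  p <- ggplot2::ggplot(prevalence,
                       ggplot2::aes(x = stats::reorder(.data$attribute,
                                                       .data$prevalence),
                                    y = .data$prevalence,
                                    fill = .data$payer)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Lifetime prevalence (%)", fill = "Cohort") +
    ggplot2::theme_minimal()
  if (!is.null(targets)) {
    long <- tidyr::pivot_longer(targets, -"attribute", names_to = "payer",
                                values_to = "prevalence")
    p <- p + ggplot2::geom_point(data = long, shape = 4, size = 2,
                                 position = ggplot2::position_dodge(0.9),
                                 show.legend = FALSE)
  }
  p
}

#' @export
autoplot.scd_calibration <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$target, y = .data$achieved,
                               colour = .data$converged)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Target lifetime prevalence (%)",
                  y = "Simulated lifetime prevalence (%)",
                  colour = "Within tolerance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scd_cea <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$qaly, y = .data$cost_total,
                               colour = .data$strategy)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Mean discounted QALYs",
                  y = sprintf("Mean discounted cost (%s perspective)",
                              object$perspective),
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scd_psa <- function(object, ...) {
  cloud <- ggplot2::ggplot(object$draws,
                           ggplot2::aes(x = .data$delta_qaly,
                                        y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost") +
    ggplot2::theme_minimal()
  cloud
}

#' Cost-effectiveness acceptability curve
#' @param psa An `scd_psa`.
#' @return A ggplot.
#' @export
plot_ceac <- function(psa) {
  ggplot2::ggplot(psa$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}
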