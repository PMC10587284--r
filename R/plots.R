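#' Plot annual fleet-mean scores with standard error bars
#'
#' Time series of mean technical efficiency, capacity utilisation and
#' unbiased capacity utilisation per strategy, with +/- 1 standard error
#' bars, faceted by metric.
#'
#' @param object A [annual_means()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dea_annual <- function(object, ...) {
  metric_labels <- c(te = "Technical efficiency",
                     cu = "Capacity utilisation",
                     ucu = "Unbiased capacity utilisation")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$year, y = .data$mean,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$metric,
                        labeller = ggplot2::as_labeller(metric_labels),
                        ncol = 1) +
    ggplot2::labs(x = "Year", y = "Fleet mean score",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot cumulative Malmquist indices
#'
#' Cumulative efficiency change, technical change and productivity change
#' chained from the base year (= 1), per strategy.
#'
#' @param object A [cumulate_malmquist()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.malmquist_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("cum_ec", "cum_tc", "cum_pc"),
                              names_to = "index", values_to = "value")
  long$index <- factor(long$index, c("cum_ec", "cum_tc", "cum_pc"),
                       c("EC", "TC", "PC"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year_to, y = .data$value,
                                     colour = .data$index)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$strategy) +
    ggplot2::labs(x = "Year", y = "Cumulative change (base year = 1)",
                  colour = "Index") +
    ggplot2::theme_minimal()
}

#' Residual plots for a second-stage model
#'
#' Residuals against fitted values, the visual check behind the
#' heteroskedasticity diagnostic.
#'
#' @param object A [fit_ucu_ols()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ucu_fit <- function(object, ...) {
  d <- tibble::tibble(fitted = stats::fitted(object$fit),
                      residual = stats::residuals(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Fitted", y = "Residual") +
    ggplot2::theme_minimal()
}
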