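#' Plot a deterministic SIR trajectory
#'
#' Compartment curves (persons) over time.
#'
#' @param object A `sir_trajectory` from [simulate_deterministic()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sir_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$compartments, c("S", "I", "R"),
                              names_to = "compartment", values_to = "count")
  long$compartment <- factor(long$compartment, levels = c("S", "I", "R"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$count,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "persons", colour = NULL)
}

#' Plot a fitted trajectory against the observed counts
#'
#' Observed per-bin counts as points, the fitted model trajectory as a
#' line, with the relative fit measure in the subtitle.
#'
#' @param object A `sir_fit` or `spline_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.popsir_fit <- function(object, ...) {
  d <- object$trajectory
  d$mid <- (d$bin_start + d$bin_end) / 2
  subtitle <- sprintf("relative fit measure %.3g", object$fit_measure)
  if (object$model_kind == "sir" && !is.null(object$derived)) {
    subtitle <- sprintf("%s; R0 %.3g, infectious period %.3g d", subtitle,
                        object$derived$R0, object$derived$infectious_period)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$count), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted_count),
                       colour = if (object$model_kind == "sir")
                         "forestgreen" else "darkorange") +
    ggplot2::labs(x = "time (days)", y = "events per bin",
                  title = paste(toupper(object$model_kind), "fit"),
                  subtitle = subtitle)
}

#' Plot the two arms of a calibration comparison
#'
#' Scatter of SIR versus spline fit measures per series, one panel per
#' arm, with the y = x line; points below the line are series the
#' mechanistic model fits better.
#'
#' @param object A `calibration_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_comparison <- function(object, ...) {
  arms <- purrr::compact(list(catalog = object$catalog,
                              simulations = object$simulations))
  d <- dplyr::bind_rows(purrr::map(arms, tidy), .id = "arm")
  ggplot2::ggplot(d, ggplot2::aes(.data$fit_measure_spline,
                                  .data$fit_measure_sir,
                                  colour = .data$well_captured)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "spline fit measure", y = "SIR fit measure",
                  colour = "well captured")
}
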