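#' Plot a Kaplan-Meier curve with its confidence band
#'
#' Step plot of the survival estimate with the (log-log) confidence band as
#' a stepped ribbon.
#'
#' @param object An `avr_survcurve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot avr_survcurve
#' @export
autoplot.avr_survcurve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      stat = "identity", alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since operation", y = "Survival probability")
}

#' Plot an analytic expected-survival curve
#'
#' @param object An `avr_expected_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot avr_expected_curve
#' @export
autoplot.avr_expected_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since operation",
                  y = "Expected survival probability")
}

#' Overlay the cohort curve on the matched-population reference curve
#'
#' The standard comparison figure: the cohort Kaplan-Meier estimate (solid,
#' with confidence band) against the Monte Carlo matched general-population
#' reference (dashed).
#'
#' @param cohort_km An `avr_survcurve` of the cohort.
#' @param reference_km An `avr_survcurve` from [reference_km()].
#' @return A ggplot object.
#' @export
plot_reference_compare <- function(cohort_km, reference_km) {
  both <- dplyr::bind_rows(
    dplyr::mutate(dplyr::as_tibble(cohort_km), arm = "cohort"),
    dplyr::mutate(dplyr::as_tibble(reference_km), arm = "matched population"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$time, y = .data$surv,
                                     linetype = .data$arm)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper,
                   group = .data$arm),
      stat = "identity", alpha = 0.15, na.rm = TRUE) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since operation", y = "Survival probability",
                  linetype = NULL)
}

#' Plot scaled Schoenfeld residuals against time per predictor
#'
#' @param object An `avr_ph_diagnostic`.
#' @param ... Unused.
#' @return A ggplot object, one facet per model term.
#' @method autoplot avr_ph_diagnostic
#' @export
autoplot.avr_ph_diagnostic <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$time, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Time (KM-transformed)",
                  y = "Scaled Schoenfeld residual")
}
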