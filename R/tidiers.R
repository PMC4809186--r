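#' Tidy a fitted risk model
#'
#' @param x An `avr_regression`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`
#'   (OR or HR scale), `conf_low`, `conf_high`, `p`.
#' @method tidy avr_regression
#' @export
tidy.avr_regression <- function(x, ...) {
  dplyr::mutate(x$estimates, scale = x$scale)
}

#' One-row summary of a fitted risk model
#'
#' @param x An `avr_regression`.
#' @param ... Unused.
#' @return A one-row tibble: `scale`, `n`, `n_events`, `n_predictors`,
#'   `n_removed` (length of the elimination trace), `n_dropped`
#'   (incomplete records excluded).
#' @method glance avr_regression
#' @export
glance.avr_regression <- function(x, ...) {
  tibble::tibble(scale = x$scale, n = x$n, n_events = x$n_events,
                 n_predictors = length(x$predictors),
                 n_removed = nrow(x$elimination_trace),
                 n_dropped = x$n_dropped)
}

#' @export
print.avr_regression <- function(x, ...) {
  cat("<avr_regression> ", x$scale, " scale; n = ", x$n, ", events = ",
      x$n_events, "\n", sep = "")
  print(x$estimates)
  if (nrow(x$elimination_trace) > 0) {
    cat("Eliminated:", paste(x$elimination_trace$removed, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Tidy a log-rank result
#' @param x An `avr_logrank`.
#' @param ... Unused.
#' @return The one-row result tibble with the per-group observed/expected
#'   detail joined in nested form.
#' @method tidy avr_logrank
#' @export
tidy.avr_logrank <- function(x, ...) {
  out <- dplyr::as_tibble(x)
  out$detail <- list(attr(x, "detail"))
  out
}

#' One-row summary of a survival curve
#' @param x An `avr_survcurve`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `total_weight`, `events`, `median`,
#'   `median_ci_lower`, `median_ci_upper`.
#' @method glance avr_survcurve
#' @export
glance.avr_survcurve <- function(x, ...) {
  med <- median_survival(x)
  tibble::tibble(n = attr(x, "n"), total_weight = attr(x, "total_weight"),
                 events = sum(x$n_event), median = med$median,
                 median_ci_lower = med$ci_lower,
                 median_ci_upper = med$ci_upper)
}

#' Tidy an univariate screen
#' @param x An `avr_screen`.
#' @param ... Unused.
#' @return The screen tibble with `m` and the Bonferroni `threshold` as
#'   columns.
#' @method tidy avr_screen
#' @export
tidy.avr_screen <- function(x, ...) {
  dplyr::mutate(dplyr::as_tibble(x), m = attr(x, "m"),
                threshold = attr(x, "threshold"))
}
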