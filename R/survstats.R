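#' Kaplan-Meier estimate with Greenwood variance and log-log intervals
#'
#' Weighted product-limit estimate (via [survival::survfit()]) with
#' Greenwood variance and complementary log-log transformed confidence
#' intervals, which respect the \[0, 1\] range. Deaths precede censorings at
#' tied times (the universal Kaplan-Meier convention). With unit weights
#' this is the ordinary Kaplan-Meier estimator.
#'
#' @param data A data frame with one row per subject (or pseudo-subject).
#' @param time,event,weight Column names for follow-up time (years), event
#'   indicator (1 = died, 0 = censored) and optional case weight.
#' @param conf_level Confidence level (default 0.95).
#' @return An `avr_survcurve` tibble with columns `time` (including 0),
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `greenwood_var`, `ci_lower`,
#'   `ci_upper`.
#' @export
km_estimate <- function(data, time = "followup_years", event = "event",
                        weight = NULL, conf_level = 0.95) {
  if (nrow(data) == 0) abort("Kaplan-Meier estimate needs at least one subject")
  t <- data[[time]]
  e <- data[[event]]
  w <- if (is.null(weight)) rep(1, nrow(data)) else data[[weight]]
  if (any(is.na(t) | is.na(e))) abort("Missing time or event values")
  if (any(t < 0)) abort("Negative follow-up time")
  fit <- survival::survfit(
    survival::Surv(t, e) ~ 1, weights = w,
    conf.type = "log-log", conf.int = conf_level)
  out <- tibble::tibble(
    time = c(0, fit$time),
    n_risk = c(sum(w), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    surv = c(1, fit$surv),
    greenwood_var = c(0, (fit$surv * fit$std.err)^2),
    ci_lower = c(1, fit$lower),
    ci_upper = c(1, fit$upper))
  attr(out, "conf_level") <- conf_level
  attr(out, "n") <- nrow(data)
  attr(out, "total_weight") <- sum(w)
  class(out) <- c("avr_survcurve", class(out))
  out
}

# survfit's median convention: first time the (ordered, non-increasing)
# series drops to <= 0.5, with midpoint interpolation when it sits exactly
# at 0.5 before dropping further.
minmin <- function(y, x) {
  tol <- .Machine$double.eps^0.5
  keep <- !is.na(y) & y < (0.5 + tol)
  if (!any(keep)) return(NA_real_)
  x <- x[keep]
  y <- y[keep]
  if (abs(y[1] - 0.5) < tol && any(y < y[1])) {
    (x[1] + x[min(which(y < y[1]))]) / 2
  } else {
    x[1]
  }
}

#' Median survival with Brookmeyer-Crowley confidence limits
#'
#' The median is the first curve time at which the survival estimate drops
#' to 0.5 or below (undefined when the curve never reaches 0.5). Confidence
#' limits invert the pointwise log-log confidence band
#' (Brookmeyer-Crowley): the lower (upper) limit is where the lower (upper)
#' band crosses 0.5. A limit that never materialises is open and reported
#' as `NA`; [format_median()] renders open bounds with an ellipsis, as is
#' conventional in survival tables.
#'
#' @param curve An `avr_survcurve` from [km_estimate()].
#' @return An `avr_median` one-row tibble: `median`, `ci_lower`,
#'   `ci_upper` (years; `NA` = undefined/open).
#' @export
median_survival <- function(curve) {
  out <- tibble::tibble(
    median = minmin(curve$surv, curve$time),
    ci_lower = minmin(curve$ci_lower, curve$time),
    ci_upper = minmin(curve$ci_upper, curve$time))
  class(out) <- c("avr_median", class(out))
  out
}

#' Render a median estimate as `"m (l to u)"` with open bounds as an ellipsis
#'
#' @param med An `avr_median` row.
#' @param digits Significant digits.
#' @return A character scalar such as `"10.9 (10.5 to 11.8)"` or
#'   `"15.1 (13.5, …)"`.
#' @export
format_median <- function(med, digits = 3) {
  f <- function(x) ifelse(is.na(x), "…", format(signif(x, digits)))
  m <- ifelse(is.na(med$median), "…", format(signif(med$median, digits)))
  if (is.na(med$ci_upper)) {
    paste0(m, " (", f(med$ci_lower), ", …)")
  } else {
    paste0(m, " (", f(med$ci_lower), " to ", f(med$ci_upper), ")")
  }
}

# Weighted k-group log-rank machinery shared by logrank() and
# restricted_reference_compare(). Inputs are parallel vectors.
logrank_compute <- function(t, e, g, w) {
  g <- as.factor(g)
  k <- nlevels(g)
  levs <- levels(g)
  wg_tot <- vapply(levs, function(l) sum(w[g == l]), numeric(1))
  if (any(wg_tot <= 0)) {
    abort(paste0("Log-rank: group '", levs[which(wg_tot <= 0)[1]],
                 "' has zero total weight"))
  }
  ut <- sort(unique(t[e == 1]))
  detail <- tibble::tibble(group = levs, n = as.integer(table(g)),
                           total_weight = wg_tot,
                           observed = 0, expected = 0)
  if (length(ut) == 0) {
    return(list(statistic = 0, df = k - 1L, p = 1, detail = detail))
  }
  nt <- length(ut)
  Y <- matrix(0, nt, k)
  D <- matrix(0, nt, k)
  for (j in seq_len(k)) {
    sel <- g == levs[j]
    tj <- t[sel]
    wj <- w[sel]
    o <- order(tj)
    cw <- c(0, cumsum(wj[o]))
    # weight with time < ut[i]  ->  at risk = total - that
    Y[, j] <- wg_tot[j] - cw[findInterval(ut, tj[o], left.open = TRUE) + 1]
    dj <- sel & e == 1
    if (any(dj)) {
      tab <- tapply(w[dj], factor(t[dj], levels = ut), sum)
      D[, j] <- ifelse(is.na(tab), 0, tab)
    }
  }
  Ytot <- rowSums(Y)
  Dtot <- rowSums(D)
  E <- Y * (Dtot / Ytot)
  U <- colSums(D - E)
  V <- matrix(0, k, k)
  corr <- ifelse(Ytot > 1, (Ytot - Dtot) / (Ytot - 1), 0)
  for (i in seq_len(nt)) {
    p <- Y[i, ] / Ytot[i]
    V <- V + Dtot[i] * corr[i] * (diag(p, k) - tcrossprod(p))
  }
  idx <- seq_len(k - 1)
  stat <- drop(t(U[idx]) %*% pinv(V[idx, idx, drop = FALSE]) %*% U[idx])
  stat <- max(stat, 0)
  detail$observed <- colSums(D)
  detail$expected <- colSums(E)
  list(statistic = stat, df = k - 1L,
       p = pchisq(stat, k - 1L, lower.tail = FALSE), detail = detail)
}

logrank_result <- function(res, horizon = NA_real_, mode = NA_character_) {
  out <- tibble::tibble(statistic = res$statistic, df = res$df, p = res$p,
                        horizon = horizon)
  attr(out, "detail") <- res$detail
  attr(out, "mode") <- mode
  class(out) <- c("avr_logrank", class(out))
  out
}

#' (Weighted) log-rank test for equality of survivor functions
#'
#' Standard k-group log-rank chi-squared with `df = k - 1`; when a weight
#' column is supplied, the at-risk and event sums are weighted. With unit
#' weights this is the classic (Mantel-Cox) log-rank test.
#'
#' @param data One row per subject.
#' @param time,event,group,weight Column names; `weight` optional.
#' @return An `avr_logrank` one-row tibble (`statistic`, `df`, `p`,
#'   `horizon = NA`); the per-group observed/expected table is in the
#'   `"detail"` attribute.
#' @export
logrank <- function(data, time = "followup_years", event = "event",
                    group = "group", weight = NULL) {
  g <- data[[group]]
  if (length(unique(g[!is.na(g)])) < 2) {
    abort("Log-rank needs at least two non-empty groups")
  }
  keep <- !is.na(g)
  w <- if (is.null(weight)) rep(1, nrow(data)) else data[[weight]]
  res <- logrank_compute(data[[time]][keep], data[[event]][keep],
                         g[keep], w[keep])
  logrank_result(res)
}

censor_at <- function(t, e, tau) {
  e[t > tau] <- 0L
  t[t > tau] <- tau
  list(time = t, event = e)
}

#' Horizon-restricted comparison of a cohort against its MC reference
#'
#' Administratively censors both arms at `tau` years (events after `tau`
#' become censorings at `tau`) and runs a two-group log-rank test of the
#' cohort against its matched Monte Carlo reference sample. `tau = NULL`
#' compares over the entire follow-up period.
#'
#' Two aggregation modes for the reference arm:
#' \describe{
#'   \item{`"pooled"` (default)}{every pseudo-subject enters with weight 1.
#'     Because the Monte Carlo runs are independent draws from each
#'     patient's life-table law, the pooled pseudo-subjects are genuinely
#'     independent observations and the test is correctly calibrated; as
#'     the number of runs grows it converges to the classic one-sample
#'     log-rank test against the known population hazard.}
#'   \item{`"effective"`}{pseudo-subjects keep their `1 / runs` weights, so
#'     the reference arm's effective size equals the cohort's. This mode is
#'     conservative: the hypergeometric variance treats the (nearly
#'     deterministic) reference arm as if it carried a full cohort's worth
#'     of sampling noise, roughly doubling the variance and deflating the
#'     statistic.}
#' }
#'
#' @param cohort A cohort table (`followup_years`, `event`).
#' @param reference An `avr_reference_sample` built from the same cohort.
#' @param tau Restriction horizon in years (> 0), or `NULL` for full
#'   follow-up.
#' @param mode `"pooled"` or `"effective"` (see Details).
#' @return An `avr_logrank` one-row tibble with the `horizon` column set.
#' @export
restricted_reference_compare <- function(cohort, reference, tau = NULL,
                                         mode = c("pooled", "effective")) {
  mode <- match.arg(mode)
  if (!is.null(tau) && tau <= 0) abort("tau must be > 0 (or NULL)")
  ct <- cohort$followup_years
  ce <- as.integer(cohort$event)
  rt <- reference$time
  re <- as.integer(reference$event)
  if (!is.null(tau)) {
    a <- censor_at(ct, ce, tau)
    b <- censor_at(rt, re, tau)
    ct <- a$time; ce <- a$event; rt <- b$time; re <- b$event
  }
  rw <- if (mode == "effective") reference$weight else rep(1, nrow(reference))
  res <- logrank_compute(
    c(ct, rt), c(ce, re),
    rep(c("cohort", "reference"), c(length(ct), length(rt))),
    c(rep(1, length(ct)), rw))
  logrank_result(res, horizon = if (is.null(tau)) NA_real_ else tau,
                 mode = mode)
}

#' Write a survival curve to CSV
#' @param curve An `avr_survcurve` (or `avr_expected_curve`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  readr::write_csv(dplyr::as_tibble(curve), path)
  invisible(path)
}
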