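#' Risk models: logistic (early mortality) and Cox (long-term mortality)
#'
#' Model-fitting layer mirroring the registry analyses: multiple logistic
#' regression for in-hospital/30-day death, Cox proportional hazards for
#' long-term mortality, stepwise backward elimination, Bonferroni-screened
#' univariate analysis and proportional-hazards diagnostics.
#'
#' @name models
NULL

default_predictors <- function() {
  c("age_at_op", "sex", "smoker", "procedure_group", "lvf_class",
    "lung_disease", "ckd", "arteriopathy_extracardiac", "arrhythmia_preop",
    "hypertension_treated", "diabetes_treated", "euroscore_class")
}

# Term-level Wald chi-squared statistics from coefficients and vcov, using
# the model-matrix assign map so multi-level factors are tested jointly.
term_wald <- function(fit) {
  labs <- attr(terms(fit), "term.labels")
  mm <- model.matrix(fit)
  asg <- attr(mm, "assign")
  b <- coef(fit)
  V <- vcov(fit)
  if (inherits(fit, "coxph")) {
    # coxph model matrix has no intercept column; assign indexes terms 1..m
    cn <- names(b)
  } else {
    cn <- colnames(mm)
  }
  rows <- lapply(seq_along(labs), function(j) {
    cols <- cn[asg == j]
    cols <- cols[cols %in% names(b)]
    cols <- cols[!is.na(b[cols])]
    if (length(cols) == 0) {
      return(tibble::tibble(term = labs[j], df = 0L, chisq = NA_real_,
                            p = NA_real_))
    }
    bj <- b[cols]
    Vj <- V[cols, cols, drop = FALSE]
    chi <- drop(t(bj) %*% pinv(Vj) %*% bj)
    tibble::tibble(term = labs[j], df = length(cols), chisq = chi,
                   p = pchisq(chi, length(cols), lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

coef_table <- function(fit, scale, conf_level = 0.95) {
  b <- coef(fit)
  b <- b[!is.na(b)]
  if (length(b) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          conf_low = numeric(), conf_high = numeric(),
                          p = numeric()))
  }
  se <- sqrt(diag(vcov(fit)))[names(b)]
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(b),
    estimate = unname(exp(b)),
    conf_low = unname(exp(b - z * se)),
    conf_high = unname(exp(b + z * se)),
    p = unname(pchisq((b / se)^2, 1, lower.tail = FALSE)))
  if (scale == "OR") out <- out[out$term != "(Intercept)", ]
  out
}

new_regression <- function(fit, scale, predictors, trace, n, n_events,
                           n_dropped) {
  structure(list(fit = fit, scale = scale, predictors = predictors,
                 estimates = coef_table(fit, scale),
                 term_tests = if (length(predictors)) term_wald(fit) else
                   tibble::tibble(term = character(), df = integer(),
                                  chisq = numeric(), p = numeric()),
                 elimination_trace = trace, n = n, n_events = n_events,
                 n_dropped = n_dropped),
            class = "avr_regression")
}

empty_trace <- function() {
  tibble::tibble(step = integer(), removed = character(),
                 p_at_removal = numeric())
}

drop_constant <- function(data, predictors) {
  keep <- vapply(predictors, function(p) {
    v <- data[[p]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  if (any(!keep)) {
    warn(paste0("Dropping constant predictor(s): ",
                paste(predictors[!keep], collapse = ", ")))
  }
  predictors[keep]
}

model_frame <- function(data, cols) {
  cc <- complete.cases(data[cols])
  if (any(!cc)) {
    inform(paste0(sum(!cc), " record(s) dropped (missing values in ",
                  "model variables); complete-case analysis"))
  }
  dplyr::as_tibble(data[cc, , drop = FALSE])
}

#' Fit a multiple logistic regression (odds-ratio scale)
#'
#' Maximum-likelihood logistic fit for a binary outcome (by default
#' in-hospital/30-day death), reporting odds ratios with Wald confidence
#' intervals. Records with missing values in the used variables are dropped
#' (complete-case, reported via a message); constant predictors are dropped
#' with a warning; perfect separation raises an explicit error.
#'
#' @param data A (covariate-coded) cohort table.
#' @param predictors Character vector of predictor column names.
#' @param outcome Binary outcome column (logical or 0/1).
#' @param conf_level Wald CI level.
#' @return An `avr_regression` (see [tidy.avr_regression()]).
#' @export
fit_logistic <- function(data, predictors, outcome = "early_death",
                         conf_level = 0.95) {
  df <- model_frame(data, c(outcome, predictors))
  predictors <- drop_constant(df, predictors)
  if (nrow(df) < 10 * max(length(predictors), 1)) {
    warn("Fewer than 10 complete cases per predictor")
  }
  y <- as.integer(df[[outcome]])
  if (!all(y %in% c(0L, 1L))) abort("Logistic outcome must be binary")
  fml <- if (length(predictors)) reformulate(predictors, response = outcome)
         else stats::as.formula(paste(outcome, "~ 1"))
  df[[outcome]] <- y
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  b <- coef(fit)
  if (!fit$converged || any(abs(b[!is.na(b)]) > 15)) {
    abort("Perfect (or quasi-perfect) separation detected in logistic fit")
  }
  new_regression(fit, "OR", predictors, empty_trace(),
                 n = nrow(df), n_events = sum(y),
                 n_dropped = nrow(data) - nrow(df))
}

#' Fit a Cox proportional hazards model (hazard-ratio scale)
#'
#' Partial-likelihood fit via [survival::coxph()] with the configured tie
#' method, reporting hazard ratios with Wald confidence intervals.
#' Complete-case handling and constant-predictor dropping as in
#' [fit_logistic()].
#'
#' @param data A (covariate-coded) cohort table.
#' @param predictors Character vector of predictor column names.
#' @param time,event Follow-up time and event columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Wald CI level.
#' @return An `avr_regression`.
#' @export
fit_cox <- function(data, predictors, time = "followup_years",
                    event = "event", ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  df <- model_frame(data, c(time, event, predictors))
  if (any(df[[time]] <= 0)) {
    abort("Cox fit requires strictly positive follow-up times")
  }
  if (sum(df[[event]]) == 0) abort("Cox fit requires at least one event")
  predictors <- drop_constant(df, predictors)
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    if (length(predictors)) paste(predictors, collapse = " + ") else "1"))
  fit <- survival::coxph(fml, data = df, ties = ties, model = TRUE,
                         x = length(predictors) > 0)
  new_regression(fit, "HR", predictors, empty_trace(),
                 n = nrow(df), n_events = sum(df[[event]]),
                 n_dropped = nrow(data) - nrow(df))
}

#' Stepwise backward elimination on term-level Wald p-values
#'
#' Starting from the full model, iteratively refits after removing the
#' single predictor with the largest term-level Wald p-value at or above
#' `alpha_out`, stopping when every retained predictor has `p < alpha_out`.
#' Ties are broken deterministically by predictor order. The full removal
#' trace is recorded; the final model is a fixed point of one further
#' elimination pass.
#'
#' @param data A (covariate-coded) cohort table.
#' @param predictors Initial predictor set, in tie-break order.
#' @param fitter `"logistic"` or `"cox"`.
#' @param alpha_out Removal threshold (default 0.05): predictors stay only
#'   with `p < alpha_out`.
#' @param ... Passed to [fit_logistic()] / [fit_cox()] (`outcome`, `time`,
#'   `event`, `ties`, ...).
#' @return An `avr_regression` whose `elimination_trace` lists
#'   `(step, removed, p_at_removal)`.
#' @export
backward_eliminate <- function(data, predictors,
                               fitter = c("logistic", "cox"),
                               alpha_out = 0.05, ...) {
  fitter <- match.arg(fitter)
  if (alpha_out <= 0 || alpha_out > 1) abort("alpha_out must be in (0, 1]")
  fit_fun <- if (fitter == "logistic") fit_logistic else fit_cox
  preds <- predictors
  trace <- empty_trace()
  step <- 0L
  repeat {
    res <- fit_fun(data, preds, ...)
    preds <- res$predictors # constants may have been dropped
    if (length(preds) == 0) break
    tw <- res$term_tests
    pvals <- tw$p[match(preds, tw$term)]
    pvals[is.na(pvals)] <- 1
    worst <- which(pvals == max(pvals))[1] # first-listed wins ties
    if (alpha_out >= 1 || pvals[worst] < alpha_out) break
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, removed = preds[worst], p_at_removal = pvals[worst]))
    preds <- preds[-worst]
    if (length(preds) == 0) {
      res <- fit_fun(data, preds, ...)
      break
    }
  }
  res$elimination_trace <- trace
  res
}

#' Bonferroni-screened univariate analysis
#'
#' One single-predictor fit per covariate; a predictor is flagged iff its
#' term-level p-value is below `alpha / m`, where `m` is the number of
#' predictors screened.
#'
#' @param data A (covariate-coded) cohort table.
#' @param predictors Covariates to screen.
#' @param alpha Family-wise level (default 0.05).
#' @param fitter `"logistic"` or `"cox"`.
#' @param ... Passed to the fitter.
#' @return An `avr_screen` tibble: `term`, `df`, `chisq`, `p`, `estimate`
#'   (OR/HR for single-coefficient terms, `NA` for multi-level factors),
#'   `flagged`; the adjusted threshold and `m` are attributes.
#' @export
univariate_screen <- function(data, predictors, alpha = 0.05,
                              fitter = c("logistic", "cox"), ...) {
  fitter <- match.arg(fitter)
  m <- length(predictors)
  if (m < 1) abort("univariate_screen needs at least one predictor")
  fit_fun <- if (fitter == "logistic") fit_logistic else fit_cox
  rows <- lapply(predictors, function(p) {
    res <- fit_fun(data, p, ...)
    tw <- res$term_tests
    est <- if (nrow(res$estimates) == 1) res$estimates$estimate else NA_real_
    tibble::tibble(term = p, df = tw$df[1], chisq = tw$chisq[1],
                   p = tw$p[1], estimate = est)
  })
  out <- dplyr::bind_rows(rows)
  out$flagged <- !is.na(out$p) & out$p < alpha / m
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- alpha / m
  class(out) <- c("avr_screen", class(out))
  out
}

#' Proportional-hazards diagnostic (scaled Schoenfeld residual trend)
#'
#' Machine-checkable counterpart of the usual visual check: per-predictor
#' correlation test of the scaled Schoenfeld residuals against (KM-
#' transformed) time via [survival::cox.zph()], plus the residual-vs-time
#' series for plotting.
#'
#' @param result An `avr_regression` from [fit_cox()] (or
#'   [backward_eliminate()] with `fitter = "cox"`).
#' @return An `avr_ph_diagnostic` list: `table` (term, chisq, df, p,
#'   including the global test) and `residuals` (time, term, residual).
#' @export
ph_diagnostic <- function(result) {
  if (!inherits(result$fit, "coxph")) {
    abort("ph_diagnostic needs a Cox model result")
  }
  if (result$n_events < 2) {
    abort("Proportional-hazards diagnostic needs at least two events")
  }
  zph <- survival::cox.zph(result$fit, transform = "km", terms = TRUE)
  tab <- tibble::tibble(
    term = rownames(zph$table),
    chisq = zph$table[, "chisq"],
    df = zph$table[, "df"],
    p = zph$table[, "p"])
  y <- as.matrix(zph$y)
  res <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(time = zph$time),
                     tibble::as_tibble(y, .name_repair = "minimal")),
    -"time", names_to = "term", values_to = "residual")
  structure(list(table = tab, residuals = res),
            class = "avr_ph_diagnostic")
}

#' Descriptive comparison of two patient groups
#'
#' Per-variable group summaries with significance tests: Welch two-sample
#' t-test for continuous variables, Pearson chi-squared without continuity
#' correction for categorical ones (the conventions used in surgical
#' registry descriptive tables).
#'
#' @param data A cohort table.
#' @param by Grouping column with exactly two non-missing levels.
#' @param variables Columns to compare; defaults to every column except
#'   `by`, identifiers and dates.
#' @return A tibble: `variable`, `type`, one summary column per group
#'   (`mean (sd)` or `n (%)`), `p`.
#' @export
group_compare_descriptive <- function(data, by, variables = NULL) {
  g <- as.factor(data[[by]])
  g <- droplevels(g)
  if (nlevels(g) != 2) abort("group_compare_descriptive needs exactly two groups")
  if (any(table(g) == 0)) abort("Empty group")
  variables <- variables %||%
    setdiff(names(data), c(by, "patient_id", "op_date"))
  lev <- levels(g)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2) {
      p <- tryCatch(t.test(x ~ g)$p.value, error = function(e) NA_real_)
      s <- vapply(lev, function(l) {
        xi <- x[g == l]
        sprintf("%.1f (%.1f)", mean(xi, na.rm = TRUE), sd(xi, na.rm = TRUE))
      }, character(1))
      type <- "continuous"
    } else {
      xf <- droplevels(as.factor(x))
      tab <- table(xf, g)
      p <- if (nrow(tab) < 2) NA_real_ else
        tryCatch(chisq.test(tab, correct = FALSE)$p.value,
                 error = function(e) NA_real_)
      top <- if (is.logical(x)) "TRUE" else rownames(tab)[nrow(tab)]
      s <- vapply(lev, function(l) {
        xi <- x[g == l]
        n1 <- sum(as.character(xi) == top, na.rm = TRUE)
        sprintf("%d (%.1f%%)", n1, 100 * n1 / sum(!is.na(xi)))
      }, character(1))
      type <- "categorical"
    }
    out <- tibble::tibble(variable = v, type = type)
    out[[lev[1]]] <- s[1]
    out[[lev[2]]] <- s[2]
    out$p <- p
    out
  })
  dplyr::bind_rows(rows)
}
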