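# Expand a 2x2 outcome-by-group table into one row per patient.
expand_2x2 <- function(events_a, n_a, events_b, n_b,
                       labels = c("AVR", "AVR_CABG")) {
  tibble::tibble(
    group = rep(labels, c(n_a, n_b)),
    outcome = c(rep(c(1L, 0L), c(events_a, n_a - events_a)),
                rep(c(1L, 0L), c(events_b, n_b - events_b))))
}

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  d <- expand_2x2(27, 967, 41, 848)
  fit <- fit_logistic(d, "group", outcome = "outcome")
  or_closed <- (41 * 940) / (27 * 807)
  expect_equal(tidy(fit)$estimate, or_closed, tolerance = 1e-6)
  expect_equal(glance(fit)$n, 1815)
})

test_that("logistic null recovery and parameter recovery", {
  set.seed(412)
  n <- 5000
  d <- tibble::tibble(x = rbinom(n, 1, 0.5) == 1,
                      outcome = rbinom(n, 1, 0.1))
  fit <- fit_logistic(d, "x", outcome = "outcome")
  td <- tidy(fit)
  expect_true(td$conf_low < 1 && td$conf_high > 1)

  # generative early-death model: OR 1.4 per high EuroSCORE class
  n2 <- 40000
  high <- rbinom(n2, 1, 0.76) == 1
  p <- plogis(qlogis(0.03) + log(1.4) * high)
  d2 <- tibble::tibble(high = high, outcome = rbinom(n2, 1, p))
  fit2 <- fit_logistic(d2, "high", outcome = "outcome")
  expect_lt(abs(tidy(fit2)$estimate - 1.4), 0.14)
})

test_that("logistic degenerate designs error or warn as documented", {
  d <- tibble::tibble(x = c(rep(TRUE, 20), rep(FALSE, 20)),
                      outcome = c(rep(1L, 20), rep(0L, 20)))
  expect_error(suppressWarnings(fit_logistic(d, "x", outcome = "outcome")),
               "separation")
  d2 <- tibble::tibble(x = TRUE, y = rbinom(30, 1, 0.5) == 1,
                       outcome = rbinom(30, 1, 0.4))
  expect_warning(fit_logistic(d2, c("x", "y"), outcome = "outcome"),
                 "constant predictor")
})

test_that("Cox fit recovers known hazard ratios", {
  set.seed(413)
  n <- 2000
  x <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, 0.1 * 2^x)
  d <- tibble::tibble(followup_years = t, event = 1L, x = x == 1)
  fit <- fit_cox(d, "x")
  expect_lt(abs(tidy(fit)$estimate - 2), 0.2)

  # invariance to rescaling follow-up time
  d_scaled <- dplyr::mutate(d, followup_years = followup_years * 3.7)
  fit_s <- fit_cox(d_scaled, "x")
  expect_equal(tidy(fit_s)$estimate, tidy(fit)$estimate, tolerance = 1e-8)

  expect_warning(fit_cox(dplyr::mutate(d, z = TRUE), c("x", "z")),
                 "constant predictor")
  expect_error(fit_cox(dplyr::mutate(d, event = 0L), "x"), "at least one event")
  expect_error(fit_cox(dplyr::mutate(d, followup_years = 0), "x"),
               "positive follow-up")
})

test_that("Cox fit recovers the generative excess hazard ratios", {
  # identifiability config: negligible population hazard, excess dominates
  lt <- flat_lifetable(0.002, ages = 60:110, years = 1990:2030)
  cfg <- synthetic_config(
    n_patients = 5000, seed = 414,
    op_year_range = c(1996L, 2011L), admin_censor_date = "2013-07-31",
    covariate_prevalences = c(
      ckd = 0.15, lung_disease = 0.141, severe_lvf = 0.15,
      current_smoker = 0.15, former_smoker = 0.30, diabetes = 0.12,
      hypertension = 0.55, arrhythmia = 0.10, arteriopathy = 0.10),
    baseline_excess_hazard = 0.06,
    early_death_base_prob = 0, loss_to_followup_prob = 0)
  coh <- derive_covariates(generate_cohort(cfg, lt)$cohort)
  coh$severe_lvf <- coh$lvf_class == "severe"
  coh$current_smoker <- coh$smoker == "current"
  coh$former_smoker <- coh$smoker == "former"
  fit <- fit_cox(coh, c("ckd", "severe_lvf", "current_smoker",
                        "former_smoker", "lung_disease", "diabetes_treated",
                        "hypertension_treated", "arrhythmia_preop",
                        "arteriopathy_extracardiac"))
  td <- tidy(fit)
  truth <- c(ckdTRUE = 1.8, severe_lvfTRUE = 1.6, current_smokerTRUE = 1.5)
  for (nm in names(truth)) {
    est <- td$estimate[td$term == nm]
    expect_lt(abs(est - truth[[nm]]) / truth[[nm]], 0.15)
  }
})

test_that("backward elimination removes noise, keeps signal, and traces", {
  set.seed(415)
  n <- 1500
  x <- rbinom(n, 1, 0.5) == 1
  noise <- rbinom(n, 1, 0.5) == 1
  t <- rexp(n, 0.1 * ifelse(x, 3, 1))
  d <- tibble::tibble(followup_years = t, event = 1L, x = x, noise = noise)

  res <- backward_eliminate(d, c("x", "noise"), fitter = "cox")
  expect_equal(res$elimination_trace$removed, "noise")
  expect_true(all(res$term_tests$p < 0.05))

  # threshold 1 removes nothing
  res1 <- backward_eliminate(d, c("x", "noise"), fitter = "cox",
                             alpha_out = 1)
  expect_equal(nrow(res1$elimination_trace), 0)
  expect_equal(sort(res1$predictors), c("noise", "x"))

  # noise removed first in most replicates
  removed_first <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    n <- 400
    x <- rbinom(n, 1, 0.5) == 1
    noise <- rbinom(n, 1, 0.5) == 1
    t <- rexp(n, 0.1 * ifelse(x, 3, 1))
    d <- tibble::tibble(followup_years = t, event = 1L, x = x, noise = noise)
    res <- backward_eliminate(d, c("x", "noise"), fitter = "cox")
    nrow(res$elimination_trace) >= 1 &&
      res$elimination_trace$removed[1] == "noise"
  }, logical(1))
  expect_gte(mean(removed_first), 0.9)
})

test_that("all-noise designs eliminate down to the null model", {
  set.seed(416)
  n <- 600
  d <- tibble::tibble(
    outcome = rbinom(n, 1, 0.2),
    a = rbinom(n, 1, 0.5) == 1, b = rbinom(n, 1, 0.5) == 1,
    c = rbinom(n, 1, 0.5) == 1)
  res <- backward_eliminate(d, c("a", "b", "c"), fitter = "logistic",
                            outcome = "outcome")
  expect_equal(length(res$predictors), 0)
  expect_equal(nrow(res$elimination_trace), 3)
  expect_equal(nrow(tidy(res)), 0)
})

test_that("Bonferroni screen thresholds and family-wise error control", {
  set.seed(417)
  n <- 800
  x <- rbinom(n, 1, 0.5) == 1
  t <- rexp(n, 0.15 * ifelse(x, 2.5, 1))
  d <- tibble::tibble(followup_years = t, event = 1L, x = x,
                      noise = rbinom(n, 1, 0.5) == 1)
  s1 <- univariate_screen(d, "x", fitter = "cox")
  expect_equal(attr(s1, "threshold"), 0.05)
  s2 <- univariate_screen(d, c("x", "noise"), alpha = 0.05, fitter = "cox")
  expect_equal(attr(s2, "threshold"), 0.025)
  expect_true(s2$flagged[s2$term == "x"])
  expect_equal(tidy(univariate_screen(d, rep("x", 1), alpha = 0.05,
                                      fitter = "cox"))$threshold, 0.05)
  # m = 10 arithmetic
  d10 <- d
  for (i in 1:9) d10[[paste0("n", i)]] <- rbinom(n, 1, 0.5) == 1
  s10 <- univariate_screen(d10, c("x", paste0("n", 1:9)), fitter = "cox")
  expect_equal(attr(s10, "threshold"), 0.005)

  # family-wise false-flag rate under the global null
  fwer <- vapply(1:150, function(i) {
    set.seed(2000 + i)
    m <- 10
    n <- 120
    dd <- tibble::tibble(outcome = rbinom(n, 1, 0.3))
    for (j in seq_len(m)) dd[[paste0("p", j)]] <- rbinom(n, 1, 0.5) == 1
    sc <- univariate_screen(dd, paste0("p", seq_len(m)),
                            fitter = "logistic", outcome = "outcome")
    any(sc$flagged)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 150)
  expect_lte(mean(fwer), 0.05 + 2 * se)
})

test_that("proportional-hazards diagnostic is calibrated and powered", {
  # null: proportional hazards, few false flags
  flagged_null <- vapply(1:60, function(i) {
    set.seed(3000 + i)
    n <- 300
    x <- rbinom(n, 1, 0.5) == 1
    d <- tibble::tibble(followup_years = rexp(n, 0.1 * ifelse(x, 2, 1)),
                        event = 1L, x = x)
    ph <- ph_diagnostic(fit_cox(d, "x"))
    ph$table$p[ph$table$term == "x"] < 0.05
  }, logical(1))
  expect_lte(mean(flagged_null), 0.12)

  # crossing hazards: effect reverses at t = 5
  flagged_cross <- vapply(1:25, function(i) {
    set.seed(4000 + i)
    n <- 2000
    x <- rbinom(n, 1, 0.5) == 1
    h1 <- 0.12 * ifelse(x, 2, 1)
    t1 <- rexp(n, h1)
    h2 <- 0.12 * ifelse(x, 0.5, 1)
    t <- ifelse(t1 <= 5, t1, 5 + rexp(n, h2))
    d <- tibble::tibble(followup_years = t, event = 1L, x = x)
    ph <- ph_diagnostic(fit_cox(d, "x"))
    ph$table$p[ph$table$term == "x"] < 0.05
  }, logical(1))
  expect_gte(mean(flagged_cross), 0.8)

  # degenerate input
  d1 <- tibble::tibble(followup_years = c(1, 2, 3), event = c(1L, 0L, 0L),
                       x = c(TRUE, FALSE, TRUE))
  expect_error(ph_diagnostic(suppressWarnings(fit_cox(d1, "x"))),
               "two events")
})

test_that("descriptive group comparison reproduces printed 2x2 p-values", {
  # in-hospital death by procedure
  d1 <- expand_2x2(27, 967, 41, 848)
  tab1 <- group_compare_descriptive(d1, by = "group",
                                    variables = "outcome")
  expect_equal(round(tab1$p, 3), 0.022)
  # reoperation for bleeding by procedure
  d2 <- expand_2x2(54, 967, 67, 848)
  tab2 <- group_compare_descriptive(d2, by = "group",
                                    variables = "outcome")
  expect_equal(round(tab2$p, 3), 0.048)

  # identical groups: t-test p = 1
  set.seed(418)
  x <- rnorm(50)
  d3 <- tibble::tibble(g = rep(c("a", "b"), each = 50), v = c(x, x))
  tab3 <- group_compare_descriptive(d3, by = "g", variables = "v")
  expect_equal(tab3$p, 1, tolerance = 1e-9)
  expect_equal(tab3$type, "continuous")

  expect_error(group_compare_descriptive(
    tibble::tibble(g = "a", v = 1), by = "g"), "two groups")
})
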