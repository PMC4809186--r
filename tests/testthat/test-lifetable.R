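test_that("life table construction, domain checks and hole detection", {
  lt <- lifetable(tibble::tibble(
    age = c(65L, 66L, 65L, 66L), sex = "male",
    year = c(1996L, 1996L, 1997L, 1997L), qx = c(0.01, 0.02, 0.011, 0.021)))
  expect_equal(lifetable_age_max(lt), 66L)
  expect_equal(annual_death_prob(lt, 66, "male", 1997), 0.021)

  bad <- tibble::tibble(age = 65L, sex = "male", year = 1996L, qx = 1.2)
  expect_error(lifetable(bad), "qx outside")
  hole <- tibble::tibble(age = c(65L, 66L, 65L), sex = "male",
                         year = c(1996L, 1996L, 1997L), qx = 0.01)
  expect_error(lifetable(hole), "missing \\(age 66, male, 1997\\)")
  dup <- tibble::tibble(age = c(65L, 65L), sex = "male", year = 1996L,
                        qx = 0.01)
  expect_error(lifetable(dup), "Duplicate")
})

test_that("lookups clamp at the table edges and unknown sex errors", {
  lt <- fun_lifetable(function(a, s, y) min(0.001 * (a - 59), 1),
                      ages = 60:100, years = 1996:2013)
  expect_equal(annual_death_prob(lt, 75, "male", 2000), 0.016)
  # age clamp to the terminal row
  expect_message(
    expect_equal(annual_death_prob(lt, 121, "male", 2000),
                 annual_death_prob(lt, 100, "male", 2000)),
    "clamped")
  # year clamp to nearest covered year
  expect_equal(annual_death_prob(lt, 70, "female", 1990, quiet = TRUE),
               annual_death_prob(lt, 70, "female", 1996))
  expect_equal(annual_death_prob(lt, 70, "female", 2020, quiet = TRUE),
               annual_death_prob(lt, 70, "female", 2013))
  expect_error(annual_death_prob(lt, 70, "other", 2000), "Sex not covered")
})

test_that("CSV round-trip preserves the table", {
  lt <- flat_lifetable(0.05, ages = 65:70, years = 2000:2002)
  path <- tempfile(fileext = ".csv")
  write_lifetable(lt, path)
  lt2 <- load_lifetable(path)
  expect_equal(dplyr::as_tibble(lt2), dplyr::as_tibble(lt))
})

test_that("generated Gompertz table matches the scalar formula", {
  b <- -log(1 - 0.01) # hazard giving q = 0.01 at the first age
  lt <- generate_lifetable(
    shape = list(gompertz_b = b, gompertz_c = 1.1, sex_ratio = 1,
                 year_drift = 1),
    age_range = c(65L, 100L), year_range = c(2000L, 2005L))
  expect_equal(annual_death_prob(lt, 65, "female", 2000), 0.01, tolerance = 1e-12)
  expect_equal(annual_death_prob(lt, 75, "female", 2003),
               1 - exp(-b * 1.1^10), tolerance = 1e-12)
  # no-drift identity across years and sex symmetry
  expect_equal(annual_death_prob(lt, 80, "male", 2000),
               annual_death_prob(lt, 80, "male", 2005))
  expect_equal(annual_death_prob(lt, 80, "male", 2002),
               annual_death_prob(lt, 80, "female", 2002))
  # monotone non-decreasing in age for fixed sex/year
  q <- annual_death_prob(lt, 65:100, "male", 2001)
  expect_true(all(diff(q) >= 0))
  expect_error(generate_lifetable(shape = list(
    gompertz_b = 0.01, gompertz_c = 0.9, sex_ratio = 1, year_drift = 1)),
    "gompertz_c")
  expect_error(generate_lifetable(shape = list(
    gompertz_b = -1, gompertz_c = 1.1, sex_ratio = 1, year_drift = 1)),
    "positive")
})

test_that("expected survival: closed-form products and hand-computed means", {
  lt <- flat_lifetable(0.1)
  coh <- make_cohort(list())
  ec <- expected_survival_analytic(lt, coh, horizon = 3, mode = "ederer1")
  expect_equal(ec$survival, c(1, 0.9, 0.81, 0.729))

  lt0 <- flat_lifetable(0)
  ec0 <- expected_survival_analytic(lt0, coh, horizon = 5, mode = "ederer1")
  expect_equal(ec0$survival, rep(1, 6))

  # two patients with year-1 q of 0.0 (female) and 0.2 (male)
  lt2 <- fun_lifetable(function(a, s, y) if (s == "male") 0.2 else 0)
  coh2 <- make_cohort(list(sex = "female"), list(sex = "male"))
  ec2 <- expected_survival_analytic(lt2, coh2, horizon = 1, mode = "ederer1")
  expect_equal(ec2$survival[2], (1.0 + 0.8) / 2)

  expect_error(expected_survival_analytic(lt, coh[0, ], horizon = 3), "Empty")
  expect_error(expected_survival_analytic(lt, coh, horizon = 0), "horizon")
})

test_that("expected curves are monotone and match a brute-force loop", {
  set.seed(402)
  for (rep in 1:5) {
    lt <- fun_lifetable(function(a, s, y) runif(1, 0, 0.3),
                        ages = 64:95, years = 1995:2014)
    n <- 8
    coh <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      patient_row(patient_id = paste0("P", i),
                  age_at_op = runif(1, 65, 85),
                  sex = sample(c("male", "female"), 1),
                  op_date = as.Date("1996-01-01") + floor(runif(1, 0, 5000)))
    }))
    attr(coh, "admin_censor_date") <- as.Date("2013-07-31")
    horizon <- 10
    ec1 <- expected_survival_analytic(lt, coh, horizon, mode = "ederer1")
    ecc <- expected_survival_analytic(lt, coh, horizon, mode = "conditional")

    # brute force, one patient-year at a time
    S <- matrix(1, n, horizon + 1)
    for (i in seq_len(n)) {
      for (t in seq_len(horizon)) {
        q <- annual_death_prob(lt, floor(coh$age_at_op[i]) + t - 1,
                               coh$sex[i],
                               as.integer(format(coh$op_date[i], "%Y")) + t - 1,
                               quiet = TRUE)
        S[i, t + 1] <- S[i, t] * (1 - q)
      }
    }
    expect_equal(ec1$survival, colMeans(S), tolerance = 1e-12)

    cens <- as.numeric(as.Date("2013-07-31") - coh$op_date) / 365.25
    scond <- numeric(horizon + 1)
    scond[1] <- 1
    for (t in seq_len(horizon)) {
      at <- cens >= t
      Y <- sum(S[at, t])
      d <- sum(S[at, t] - S[at, t + 1])
      scond[t + 1] <- scond[t] * (if (Y > 0) 1 - d / Y else 1)
    }
    expect_equal(ecc$survival, scond, tolerance = 1e-12)

    expect_true(all(diff(ec1$survival) <= 1e-12))
    expect_true(all(diff(ecc$survival) <= 1e-12))
    expect_equal(ec1$survival[1], 1)
  }
})

test_that("an immortal patient can only raise the Ederer-I cohort average", {
  lt <- fun_lifetable(function(a, s, y) if (s == "male") runif(1, 0, 0.4) else 0)
  set.seed(403)
  coh <- make_cohort(list(sex = "male"), list(sex = "male", age_at_op = 80))
  base <- expected_survival_analytic(lt, coh, 8, mode = "ederer1")
  plus <- expected_survival_analytic(
    lt, dplyr::bind_rows(coh, patient_row(patient_id = "P9", sex = "female")),
    8, mode = "ederer1")
  expect_true(all(plus$survival >= base$survival - 1e-12))
})
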