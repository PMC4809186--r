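#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published marginals of an elderly UK surgical AVR
#' registry cohort: ~1815 patients aged >= 65 (mean 75, sd 5.6), ~56% male,
#' operated 1996--2011 with administrative censoring at the 2013-07-31
#' linkage date, ~46.7% concomitant CABG, comorbidity prevalences matching
#' the registry's descriptive table, excess hazard ratios matching its Cox
#' model, ~3.7% in-hospital/30-day mortality and ~1.7% loss to follow-up.
#' Prevalences not printed in the registry tables (smoking, diabetes,
#' hypertension, arrhythmia, arteriopathy) use values typical of elderly UK
#' cardiac-surgery patients.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; generation is byte-reproducible given
#'   `(config, seed)`.
#' @param age_mean,age_sd,age_min Entry-age distribution: normal truncated
#'   below at `age_min`.
#' @param prop_male Probability of male sex.
#' @param op_year_range Two calendar years; operation dates are uniform over
#'   the spanned date range.
#' @param admin_censor_date Linkage date imposing administrative censoring.
#' @param prop_avr_cabg Probability of concomitant CABG.
#' @param prop_urgent Probability the operation is urgent (rest elective).
#' @param euroscore_mean,euroscore_sd Additive EuroSCORE distribution
#'   (truncated at 0).
#' @param covariate_prevalences Named Bernoulli prevalences for `ckd`,
#'   `lung_disease`, `severe_lvf`, `current_smoker`, `former_smoker`,
#'   `diabetes`, `hypertension`, `arrhythmia`, `arteriopathy`.
#' @param complication_prevalences Named prevalences for the postoperative
#'   complications `reop_bleeding`, `stroke`, `haemofiltration`.
#' @param excess_hr Named hazard ratios scaling the excess (disease-related)
#'   hazard per covariate.
#' @param baseline_excess_hazard Excess hazard (per year) for a patient with
#'   no risk covariates, added to the population hazard from the life table.
#' @param late_divergence_year,late_excess_multiplier When set, the total
#'   hazard is multiplied by `late_excess_multiplier` beyond
#'   `late_divergence_year` years after operation.
#' @param early_death_base_prob In-hospital/30-day death probability for a
#'   low-EuroSCORE patient.
#' @param early_death_or_per_euroscore_class Odds ratio on early death for
#'   the high (vs low) EuroSCORE class.
#' @param loss_to_followup_prob Probability a patient is lost to follow-up
#'   at a uniform time before the administrative horizon.
#' @return A validated `avr_synthetic_config` list.
#' @export
synthetic_config <- function(
    n_patients = 1815,
    seed = 1L,
    age_mean = 75, age_sd = 5.6, age_min = 65,
    prop_male = 0.56,
    op_year_range = c(1996L, 2011L),
    admin_censor_date = "2013-07-31",
    prop_avr_cabg = 848 / 1815,
    prop_urgent = 0.10,
    euroscore_mean = 7.0, euroscore_sd = 2.0,
    covariate_prevalences = c(
      ckd = 0.021, lung_disease = 0.141, severe_lvf = 0.059,
      current_smoker = 0.10, former_smoker = 0.45, diabetes = 0.12,
      hypertension = 0.55, arrhythmia = 0.10, arteriopathy = 0.10),
    complication_prevalences = c(
      reop_bleeding = 0.067, stroke = 0.011, haemofiltration = 0.023),
    excess_hr = c(
      ckd = 1.8, severe_lvf = 1.6, current_smoker = 1.5,
      former_smoker = 1.1, lung_disease = 1.3, diabetes = 1.3,
      hypertension = 1.2, arrhythmia = 1.4, arteriopathy = 1.4),
    baseline_excess_hazard = 0.01,
    late_divergence_year = NULL,
    late_excess_multiplier = 1,
    early_death_base_prob = 0.03,
    early_death_or_per_euroscore_class = 1.4,
    loss_to_followup_prob = 0.017) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    prop_male = prop_male, op_year_range = as.integer(op_year_range),
    admin_censor_date = as.Date(admin_censor_date),
    prop_avr_cabg = prop_avr_cabg, prop_urgent = prop_urgent,
    euroscore_mean = euroscore_mean, euroscore_sd = euroscore_sd,
    covariate_prevalences = covariate_prevalences,
    complication_prevalences = complication_prevalences,
    excess_hr = excess_hr,
    baseline_excess_hazard = baseline_excess_hazard,
    late_divergence_year = late_divergence_year,
    late_excess_multiplier = late_excess_multiplier,
    early_death_base_prob = early_death_base_prob,
    early_death_or_per_euroscore_class = early_death_or_per_euroscore_class,
    loss_to_followup_prob = loss_to_followup_prob)
  validate_synthetic_config(cfg)
  structure(cfg, class = "avr_synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  probs <- c(cfg$prop_male, cfg$prop_avr_cabg, cfg$prop_urgent,
             cfg$covariate_prevalences, cfg$complication_prevalences,
             cfg$early_death_base_prob, cfg$loss_to_followup_prob)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    abort("Synthetic config error: a probability is outside [0,1]")
  }
  if (any(cfg$excess_hr <= 0)) {
    abort("Synthetic config error: hazard ratios must be > 0")
  }
  if (cfg$baseline_excess_hazard < 0) {
    abort("Synthetic config error: baseline_excess_hazard must be >= 0")
  }
  if (cfg$n_patients < 1) abort("Synthetic config error: n_patients < 1")
  if (length(cfg$op_year_range) != 2 ||
      cfg$op_year_range[2] < cfg$op_year_range[1]) {
    abort("Synthetic config error: op_year_range must be [start, end]")
  }
  if (cfg$admin_censor_date <
      as.Date(paste0(cfg$op_year_range[1], "-01-01"))) {
    abort("Synthetic config error: admin_censor_date precedes op_year_range")
  }
  if (cfg$late_excess_multiplier <= 0) {
    abort("Synthetic config error: late_excess_multiplier must be > 0")
  }
  invisible(cfg)
}

#' Read / write a synthetic config as YAML
#'
#' @param path YAML file path.
#' @return `read_synthetic_config()` returns an `avr_synthetic_config`;
#'   `write_synthetic_config()` returns `path` invisibly.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$covariate_prevalences <- unlist(y$covariate_prevalences)
  y$complication_prevalences <- unlist(y$complication_prevalences)
  y$excess_hr <- unlist(y$excess_hr)
  do.call(synthetic_config, y)
}

#' @rdname read_synthetic_config
#' @param cfg An `avr_synthetic_config`.
#' @export
write_synthetic_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$admin_censor_date <- format(y$admin_censor_date)
  y$covariate_prevalences <- as.list(y$covariate_prevalences)
  y$complication_prevalences <- as.list(y$complication_prevalences)
  y$excess_hr <- as.list(y$excess_hr)
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

#' Generate a Gompertz-style synthetic period life table
#'
#' Annual death probabilities follow
#' `q(age, sex, year) = 1 - exp(-B * c^(age - age_min) * sex_adj * year_adj)`
#' with `sex_adj = sex_ratio` for men (1 for women) and
#' `year_adj = year_drift^(year - year_min)` capturing secular mortality
#' improvement; values are clipped to at most 1 and are monotone
#' non-decreasing in age for fixed sex and year.
#'
#' @param shape List with `gompertz_b` (baseline yearly hazard at
#'   `age_range[1]`, > 0), `gompertz_c` (age slope, > 1), `sex_ratio`
#'   (male/female hazard ratio, > 0) and `year_drift` (per-calendar-year
#'   hazard multiplier, > 0).
#' @param age_range,year_range Inclusive integer ranges to tabulate.
#' @return An `avr_lifetable`.
#' @export
generate_lifetable <- function(
    shape = list(gompertz_b = 0.009, gompertz_c = 1.097,
                 sex_ratio = 1.4, year_drift = 0.985),
    age_range = c(64L, 105L), year_range = c(1995L, 2014L)) {
  if (shape$gompertz_c <= 1) abort("Life table config error: gompertz_c must be > 1")
  if (shape$gompertz_b <= 0 || shape$sex_ratio <= 0 || shape$year_drift <= 0) {
    abort("Life table config error: rates must be positive (q would be <= 0)")
  }
  grid <- expand.grid(age = age_range[1]:age_range[2],
                      sex = c("female", "male"),
                      year = year_range[1]:year_range[2],
                      stringsAsFactors = FALSE)
  h <- shape$gompertz_b * shape$gompertz_c^(grid$age - age_range[1]) *
    ifelse(grid$sex == "male", shape$sex_ratio, 1) *
    shape$year_drift^(grid$year - year_range[1])
  grid$qx <- pmin(1 - exp(-h), 1)
  lifetable(grid)
}

#' Generate a synthetic AVR cohort with known ground truth
#'
#' Draws a registry-like cohort from `config` on top of the population
#' mortality in `lt`. Ages are truncated-normal, covariates independent
#' Bernoulli at the configured prevalences, operation dates uniform over the
#' configured years. Each patient's latent death time is drawn in continuous
#' time by inverting the piecewise-constant (one-year intervals) cumulative
#' total hazard
#' `h(u) = -log(1 - q(age+u, sex, op_year+u)) + b * exp(sum(log(HR) * x))`,
#' the whole hazard being multiplied by `late_excess_multiplier` beyond
#' `late_divergence_year` when configured. Early (in-hospital/30-day) deaths
#' follow a logistic model on the EuroSCORE class and replace the latent
#' time by a uniform (0, 30/365] time. Observation censors the latent time
#' at the administrative horizon and, for a configured fraction, at a
#' uniform loss-to-follow-up time.
#'
#' The continuous-time inversion is deliberately independent of the yearly
#' Bernoulli scheme used by [simulate_reference_cohort()], so the generator
#' never tests the Monte Carlo engine against itself; with all excess
#' parameters zero the two agree because `P(survive year) = 1 - q` exactly.
#'
#' @param config An `avr_synthetic_config`.
#' @param lt An `avr_lifetable` covering all reachable ages and years.
#' @return A list with `cohort` (schema tibble, with the
#'   `"admin_censor_date"` attribute set) and `ground_truth` (config plus
#'   per-patient latent death, censor-horizon and loss-to-follow-up times).
#' @export
generate_cohort <- function(config, lt) {
  validate_synthetic_config(config)
  with_seed(config$seed, generate_cohort_impl(config, lt))
}

generate_cohort_impl <- function(cfg, lt) {
  n <- cfg$n_patients
  # truncated normal by rejection
  age <- rnorm(n, cfg$age_mean, cfg$age_sd)
  while (any(age < cfg$age_min)) {
    i <- age < cfg$age_min
    age[i] <- rnorm(sum(i), cfg$age_mean, cfg$age_sd)
  }
  sex <- ifelse(runif(n) < cfg$prop_male, "male", "female")
  d0 <- as.Date(paste0(cfg$op_year_range[1], "-01-01"))
  d1 <- as.Date(paste0(cfg$op_year_range[2], "-12-31"))
  op_date <- d0 + floor(runif(n) * (as.numeric(d1 - d0) + 1))
  procedure <- ifelse(runif(n) < cfg$prop_avr_cabg, "AVR_CABG", "AVR")
  urgency <- ifelse(runif(n) < cfg$prop_urgent, "urgent", "elective")
  euroscore <- pmax(0, rnorm(n, cfg$euroscore_mean, cfg$euroscore_sd))

  pv <- cfg$covariate_prevalences
  draw <- function(p) runif(n) < p
  ckd <- draw(pv[["ckd"]])
  lung <- draw(pv[["lung_disease"]])
  severe_lvf <- draw(pv[["severe_lvf"]])
  diabetes <- draw(pv[["diabetes"]])
  hypertension <- draw(pv[["hypertension"]])
  arrhythmia <- draw(pv[["arrhythmia"]])
  arteriopathy <- draw(pv[["arteriopathy"]])
  u_smoke <- runif(n)
  smoker <- ifelse(u_smoke < pv[["current_smoker"]], "current",
                   ifelse(u_smoke < pv[["current_smoker"]] +
                            pv[["former_smoker"]], "former", "never"))

  # raw measurements consistent with the drawn flags (coding recovers them)
  lvef <- ifelse(severe_lvf, runif(n, 15, 29.5),
                 pmin(pmax(rnorm(n, 58, 8), 30), 85))
  creat <- ifelse(ckd, runif(n, 200, 400), pmin(exp(rnorm(n, log(90), 0.2)), 195))

  loghr <- log(cfg$excess_hr)
  lp <- loghr[["ckd"]] * ckd + loghr[["severe_lvf"]] * severe_lvf +
    loghr[["current_smoker"]] * (smoker == "current") +
    loghr[["former_smoker"]] * (smoker == "former") +
    loghr[["lung_disease"]] * lung + loghr[["diabetes"]] * diabetes +
    loghr[["hypertension"]] * hypertension +
    loghr[["arrhythmia"]] * arrhythmia +
    loghr[["arteriopathy"]] * arteriopathy
  excess <- cfg$baseline_excess_hazard * exp(lp)

  cens_horizon <- years_between(op_date, cfg$admin_censor_date)
  if (any(cens_horizon < 0)) {
    abort("Synthetic config error: an operation date falls after admin_censor_date")
  }
  U <- max(ceiling(cens_horizon), 1) + 1L
  a0 <- floor(age)
  y0 <- date_to_year(op_date)
  k <- rep(0:(U - 1), each = n)
  qpop <- matrix(annual_death_prob(lt, rep(a0, U) + k, rep(sex, U),
                                   rep(y0, U) + k, quiet = TRUE), nrow = n)
  haz <- -log(pmax(1 - qpop, 1e-12)) + excess
  if (!is.null(cfg$late_divergence_year)) {
    late <- matrix(rep(0:(U - 1), each = n) >= cfg$late_divergence_year,
                   nrow = n)
    haz <- haz * ifelse(late, cfg$late_excess_multiplier, 1)
  }
  cumhaz <- t(apply(haz, 1, cumsum))
  if (n == 1) cumhaz <- matrix(cumsum(haz[1, ]), nrow = 1)
  E <- rexp(n)
  # year index in which the cumulative hazard crosses E (U+1 = beyond grid)
  idx <- rowSums(cumhaz < E) + 1L
  prev <- ifelse(idx == 1L, 0, cumhaz[cbind(seq_len(n), pmax(idx - 1L, 1L))])
  hk <- haz[cbind(seq_len(n), pmin(idx, U))]
  latent <- ifelse(idx > U, Inf, (idx - 1L) + (E - prev) / hk)

  p_early <- plogis(qlogis(cfg$early_death_base_prob) +
                      log(cfg$early_death_or_per_euroscore_class) *
                      (euroscore > 5))
  early <- runif(n) < p_early
  ltf <- runif(n) < cfg$loss_to_followup_prob
  ltf_time <- ifelse(ltf, runif(n) * cens_horizon, Inf)

  obs_cap <- pmin(cens_horizon, ltf_time)
  time <- pmin(latent, obs_cap)
  event <- as.integer(latent <= obs_cap)
  time[early] <- runif(sum(early), 0, 30 / 365)
  event[early] <- 1L

  reop <- draw(cfg$complication_prevalences[["reop_bleeding"]])
  stroke <- draw(cfg$complication_prevalences[["stroke"]])
  haemo <- draw(cfg$complication_prevalences[["haemofiltration"]])

  cohort <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age_at_op = round(age, 1), sex = sex, op_date = op_date,
    procedure = procedure, urgency = urgency,
    multiple_valve = FALSE, other_major_nonvalve_op = FALSE,
    previous_avr = FALSE,
    euroscore = round(euroscore, 1), lvef_percent = round(lvef, 1),
    serum_creatinine = round(creat, 1),
    lung_disease = lung, diabetes_treated = diabetes,
    hypertension_treated = hypertension, smoker = smoker,
    arrhythmia_preop = arrhythmia, arteriopathy_extracardiac = arteriopathy,
    complication_reop_bleeding = reop, complication_stroke = stroke,
    complication_haemofiltration = haemo,
    early_death = early,
    followup_years = time, event = event)
  attr(cohort, "admin_censor_date") <- cfg$admin_censor_date
  ground_truth <- list(
    config = cfg,
    latent_death_years = latent,
    censor_horizon_years = cens_horizon,
    loss_to_followup_years = ltf_time,
    early_death = early,
    excess_hazard = excess)
  list(cohort = cohort, ground_truth = ground_truth)
}

#' Write the generator ground truth as a sidecar JSON
#'
#' @param ground_truth The `ground_truth` element of [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$config <- unclass(gt$config)
  gt$config$admin_censor_date <- format(gt$config$admin_censor_date)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
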