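#' Monte Carlo engine configuration
#'
#' @param runs Number of Monte Carlo runs per patient (R; default 1000, as
#'   used to build a statistically stable reference curve).
#' @param seed Integer seed. Per-patient sub-streams are derived from
#'   `seed` and the patient id, so results are reproducible and invariant
#'   to cohort row order.
#' @param censor_mode `"match_patient_horizon"` (default): each simulated
#'   counterpart is administratively censored at its source patient's own
#'   linkage horizon, keeping the comparison's follow-up opportunity equal
#'   in both arms. `"fixed_horizon"`: all counterparts censored at
#'   `fixed_horizon` years.
#' @param fixed_horizon Horizon in years (required for
#'   `censor_mode = "fixed_horizon"`).
#' @param timing Within-year death timing: `"end_of_year"` (death during
#'   year k+1 recorded at time k+1, the default) or `"mid_year"` (k+0.5).
#' @return An `avr_mc_config` list.
#' @export
mc_config <- function(runs = 1000L, seed = 1L,
                      censor_mode = c("match_patient_horizon",
                                      "fixed_horizon"),
                      fixed_horizon = NULL,
                      timing = c("end_of_year", "mid_year")) {
  censor_mode <- match.arg(censor_mode)
  timing <- match.arg(timing)
  if (runs < 1) abort("MC config error: runs must be >= 1")
  if (censor_mode == "fixed_horizon" && is.null(fixed_horizon)) {
    abort("MC config error: fixed_horizon mode requires fixed_horizon")
  }
  structure(list(runs = as.integer(runs), seed = as.integer(seed),
                 censor_mode = censor_mode, fixed_horizon = fixed_horizon,
                 timing = timing),
            class = "avr_mc_config")
}

#' Simulate one matched general-population counterpart
#'
#' Starting from the year of operation and advancing in yearly increments,
#' draws death in year `k + 1` with the life-table probability
#' `q(age + k, sex, op_year + k)`. The first success at index `k` yields an
#' event at time `k + 1` (or `k + 0.5` with mid-year timing); surviving
#' every whole year that fits inside `max_follow` yields censoring at
#' `max_follow`. Uses (and advances) R's global RNG stream.
#'
#' @param lt An `avr_lifetable`.
#' @param age,sex,op_year Matching variables of the source patient.
#' @param max_follow Administrative horizon in years (>= 0).
#' @param timing `"end_of_year"` or `"mid_year"`.
#' @return A list with `time` (years) and `event` (0/1).
#' @export
simulate_reference_subject <- function(lt, age, sex, op_year, max_follow,
                                       timing = "end_of_year") {
  if (max_follow < 0) abort("max_follow must be >= 0")
  m <- floor(max_follow)
  if (m >= 1) {
    q <- annual_death_prob(lt, floor(age) + 0:(m - 1), sex,
                           op_year + 0:(m - 1), quiet = TRUE)
    u <- runif(m)
    hit <- which(u < q)
    if (length(hit) > 0) {
      k <- hit[1]
      t <- if (timing == "mid_year") k - 0.5 else k
      return(list(time = t, event = 1L))
    }
  }
  list(time = max_follow, event = 0L)
}

#' Simulate the matched reference cohort
#'
#' Runs `cfg$runs` Monte Carlo counterparts for every patient (matched on
#' operation year, entry age and sex) and collects them as weighted
#' pseudo-subjects, each weighted `1 / runs` so the reference group's total
#' weight equals the number of source patients. Per-patient RNG sub-streams
#' are derived from `cfg$seed` and the patient id, making the output
#' reproducible, order-invariant and parallelisable.
#'
#' @param lt An `avr_lifetable`.
#' @param cohort A cohort table (needs `patient_id`, `age_at_op`, `sex`,
#'   `op_date`).
#' @param cfg An [mc_config()].
#' @param admin_censor_date Linkage date for
#'   `censor_mode = "match_patient_horizon"`; defaults to the cohort's
#'   `"admin_censor_date"` attribute.
#' @return An `avr_reference_sample` tibble with columns
#'   `source_patient_id`, `run`, `time`, `event`, `weight`.
#' @export
simulate_reference_cohort <- function(lt, cohort, cfg = mc_config(),
                                      admin_censor_date = NULL) {
  if (nrow(cohort) == 0) abort("Empty cohort: nothing to simulate")
  R <- cfg$runs
  if (cfg$censor_mode == "match_patient_horizon") {
    admin_censor_date <- admin_censor_date %||%
      attr(cohort, "admin_censor_date")
    if (is.null(admin_censor_date)) {
      abort("match_patient_horizon mode needs admin_censor_date (argument or cohort attribute)")
    }
    max_follow <- years_between(cohort$op_date, admin_censor_date)
    if (any(max_follow < 0)) abort("admin_censor_date precedes an operation date")
  } else {
    max_follow <- rep(cfg$fixed_horizon, nrow(cohort))
  }
  a0 <- floor(cohort$age_at_op)
  y0 <- date_to_year(cohort$op_date)
  half <- if (cfg$timing == "mid_year") 0.5 else 0
  res <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    m <- floor(max_follow[i])
    sub <- derive_seed(cfg$seed, cohort$patient_id[i])
    if (m >= 1) {
      q <- annual_death_prob(lt, a0[i] + 0:(m - 1), cohort$sex[i],
                             y0[i] + 0:(m - 1), quiet = TRUE)
      hitmat <- with_seed(sub, matrix(runif(R * m), R, m, byrow = TRUE) <
                            matrix(q, R, m, byrow = TRUE))
      nhit <- rowSums(hitmat)
      k <- max.col(hitmat, ties.method = "first") # first TRUE where any
      time <- ifelse(nhit > 0, k - half, max_follow[i])
      event <- as.integer(nhit > 0)
    } else {
      time <- rep(max_follow[i], R)
      event <- rep(0L, R)
    }
    res[[i]] <- tibble::tibble(
      source_patient_id = cohort$patient_id[i],
      run = seq_len(R), time = time, event = event, weight = 1 / R)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "runs") <- R
  attr(out, "mc_config") <- cfg
  class(out) <- c("avr_reference_sample", class(out))
  out
}

#' Aggregate a reference sample into a Kaplan-Meier curve
#'
#' Weighted product-limit estimate over all pseudo-subjects, using the
#' `1 / runs` weights in the at-risk and event sums; with unit weights it
#' reduces to the ordinary Kaplan-Meier estimator.
#'
#' @param sample An `avr_reference_sample`.
#' @param conf_level Confidence level for the log-log interval.
#' @return An `avr_survcurve` (see [km_estimate()]).
#' @export
reference_km <- function(sample, conf_level = 0.95) {
  if (nrow(sample) == 0) abort("Empty reference sample")
  if (sum(sample$weight) <= 0) abort("Reference sample has zero total weight")
  km_estimate(sample, time = "time", event = "event", weight = "weight",
              conf_level = conf_level)
}

#' Write a reference sample to CSV
#' @param sample An `avr_reference_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_sample <- function(sample, path) {
  readr::write_csv(dplyr::as_tibble(sample), path)
  invisible(path)
}
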