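#' Construct a period life table
#'
#' A period life table maps (integer age, sex, calendar year) to the annual
#' death probability `qx`, in the style of national (ONS-like) life tables.
#' Coverage must be rectangular per sex: every (age, year) cell present for
#' every tabulated age and year, with no duplicates.
#'
#' @param data A data frame with columns `age` (integer years), `sex`
#'   (`"male"`/`"female"`), `year` (integer calendar year) and `qx` (annual
#'   death probability in \[0, 1\]).
#' @return A `avr_lifetable` tibble with fast-lookup matrices attached.
#' @export
lifetable <- function(data) {
  need <- c("age", "sex", "year", "qx")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("Life table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  data <- dplyr::as_tibble(data[need])
  if (any(is.na(data$qx)) || any(data$qx < 0 | data$qx > 1)) {
    bad <- which(is.na(data$qx) | data$qx < 0 | data$qx > 1)[1]
    abort(paste0("Life table qx outside [0,1] at row ", bad, ": ",
                 data$qx[bad]))
  }
  bad_sex <- which(!data$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(paste0("Life table sex token invalid at row ", bad_sex[1], ": '",
                 data$sex[bad_sex[1]], "'"))
  }
  key <- paste(data$age, data$sex, data$year)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate life table cell: (",
                 key[which(duplicated(key))[1]], ")"))
  }
  qmat <- list()
  for (s in sort(unique(data$sex))) {
    d <- data[data$sex == s, ]
    ages <- sort(unique(d$age))
    years <- sort(unique(d$year))
    full <- expand.grid(age = ages, year = years)
    have <- paste(d$age, d$year)
    hole <- which(!paste(full$age, full$year) %in% have)
    if (length(hole) > 0) {
      abort(paste0("Life table coverage hole: missing (age ",
                   full$age[hole[1]], ", ", s, ", ", full$year[hole[1]], ")"))
    }
    m <- matrix(NA_real_, length(ages), length(years),
                dimnames = list(ages, years))
    m[cbind(match(d$age, ages), match(d$year, years))] <- d$qx
    qmat[[s]] <- m
  }
  out <- dplyr::arrange(data, .data$sex, .data$year, .data$age)
  attr(out, "qmat") <- qmat
  class(out) <- c("avr_lifetable", class(out))
  out
}

#' Read a period life table from CSV
#'
#' Expects columns `age`, `sex`, `year`, `qx` (one row per cell); verifies
#' the `qx` domain, duplicate keys and rectangular coverage per sex.
#'
#' @param path CSV path.
#' @return An `avr_lifetable`.
#' @export
load_lifetable <- function(path) {
  if (!file.exists(path)) abort(paste0("Life table file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_integer(), sex = readr::col_character(),
    year = readr::col_integer(), qx = readr::col_double()),
    show_col_types = FALSE)
  lifetable(x)
}

#' Highest tabulated age of a life table
#' @param lt An `avr_lifetable`.
#' @return Integer age.
#' @export
lifetable_age_max <- function(lt) max(lt$age)

#' Annual death probability lookup with edge clamping
#'
#' Returns `q(floor(age), sex, year)`. Ages above the highest tabulated age
#' use the terminal-age row; ages below the lowest use the first row; years
#' outside coverage use the nearest covered year (the practical convention
#' for national life tables with a terminal age group). Clamps are reported
#' via a single message per call unless `quiet = TRUE`.
#'
#' @param lt An `avr_lifetable`.
#' @param age,sex,year Vectors (recycled to a common length).
#' @param quiet Suppress the clamp message.
#' @return Numeric vector of annual death probabilities.
#' @export
annual_death_prob <- function(lt, age, sex, year, quiet = FALSE) {
  qmat <- attr(lt, "qmat")
  n <- max(length(age), length(sex), length(year))
  age <- rep_len(floor(age), n)
  sex <- rep_len(sex, n)
  year <- rep_len(year, n)
  out <- numeric(n)
  clamped <- 0L
  for (s in unique(sex)) {
    m <- qmat[[s]]
    if (is.null(m)) abort(paste0("Sex not covered by life table: '", s, "'"))
    idx <- which(sex == s)
    ages <- as.integer(rownames(m))
    years <- as.integer(colnames(m))
    ai <- findInterval(age[idx], ages)        # ages are consecutive integers
    yi <- match(year[idx], years)
    clamped <- clamped + sum(age[idx] > max(ages) | age[idx] < min(ages) |
                               is.na(yi))
    ai <- pmin(pmax(ai, 1L), length(ages))
    yi[is.na(yi)] <- ifelse(year[idx][is.na(yi)] < min(years), 1L,
                            length(years))
    out[idx] <- m[cbind(ai, yi)]
  }
  if (clamped > 0 && !quiet) {
    inform(paste0("annual_death_prob: ", clamped,
                  " lookup(s) clamped to the table edge"))
  }
  out
}

#' Closed-form expected survival of the matched general population
#'
#' For each patient with entry age `a`, sex `s` and operation year `y`, the
#' life-table survival over `t` whole years is
#' `S_i(t) = prod_{k=0}^{t-1} (1 - q(a+k, s, y+k))`. Two cohort-averaging
#' conventions are provided:
#' \describe{
#'   \item{`"conditional"` (default)}{the expected product-limit curve under
#'     per-patient administrative censoring: at each year `u` the cohort
#'     hazard is the ratio of expected deaths to expected at-risk among
#'     patients whose censor horizon reaches `u`,
#'     `Sbar(t) = prod_u (1 - dbar(u) / Ybar(u))`. This is the large-R limit
#'     of the Monte Carlo reference Kaplan-Meier under matched-horizon
#'     censoring, and is non-increasing by construction.}
#'   \item{`"ederer1"`}{the censor-free Ederer-I convention: the simple mean
#'     of `S_i(t)` over all patients, ignoring censor horizons.}
#' }
#' Entry age uses `floor(age_at_op)` and the attained year advances in whole
#' calendar years from the operation year.
#'
#' @param lt An `avr_lifetable`.
#' @param cohort A cohort table (needs `age_at_op`, `sex`, `op_date`).
#' @param horizon Integer number of years for the curve grid (>= 1).
#' @param mode `"conditional"` or `"ederer1"` (see Details).
#' @param admin_censor_date Administrative censoring (linkage) date used to
#'   compute per-patient horizons in `"conditional"` mode; defaults to the
#'   cohort's `"admin_censor_date"` attribute.
#' @return An `avr_expected_curve` tibble with columns `time`, `survival`
#'   and `n_at_risk` (expected weight at risk); the matrix of per-patient
#'   survival contributions is kept in the `"contributions"` attribute.
#' @export
expected_survival_analytic <- function(lt, cohort, horizon,
                                       mode = c("conditional", "ederer1"),
                                       admin_censor_date = NULL) {
  mode <- match.arg(mode)
  n <- nrow(cohort)
  if (n == 0) abort("Empty cohort: expected survival undefined")
  horizon <- as.integer(horizon)
  if (horizon < 1) abort("horizon must be >= 1 year")

  a <- floor(cohort$age_at_op)
  y <- date_to_year(cohort$op_date)
  k <- rep(0:(horizon - 1), each = n)
  q <- matrix(annual_death_prob(lt, rep(a, horizon) + k, rep(cohort$sex, horizon),
                                rep(y, horizon) + k, quiet = TRUE),
              nrow = n)
  S <- matrix(1, n, horizon + 1)               # S[, t+1] = S_i(t)
  for (h in seq_len(horizon)) S[, h + 1] <- S[, h] * (1 - q[, h])

  if (mode == "ederer1") {
    surv <- colMeans(S)
    at_risk <- rep(n, horizon + 1)
  } else {
    admin_censor_date <- admin_censor_date %||%
      attr(cohort, "admin_censor_date")
    if (is.null(admin_censor_date)) {
      abort("conditional mode needs admin_censor_date (argument or cohort attribute)")
    }
    cens <- years_between(cohort$op_date, admin_censor_date)
    if (any(cens < 0)) abort("admin_censor_date precedes an operation date")
    surv <- numeric(horizon + 1)
    at_risk <- numeric(horizon + 1)
    surv[1] <- 1
    at_risk[1] <- n
    cur <- 1
    for (u in seq_len(horizon)) {
      in_risk <- cens >= u
      Ybar <- sum(S[in_risk, u])
      dbar <- sum(S[in_risk, u] * q[in_risk, u])
      if (Ybar <= 0) {
        surv[u + 1] <- surv[u]
        at_risk[u + 1] <- 0
      } else {
        cur <- cur * (1 - dbar / Ybar)
        surv[u + 1] <- cur
        at_risk[u + 1] <- Ybar
      }
    }
  }
  out <- tibble::tibble(time = 0:horizon, survival = surv, n_at_risk = at_risk)
  attr(out, "contributions") <- S
  attr(out, "mode") <- mode
  class(out) <- c("avr_expected_curve", class(out))
  out
}

#' Write a life table to CSV
#' @param lt An `avr_lifetable` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  readr::write_csv(dplyr::as_tibble(lt[c("age", "sex", "year", "qx")]), path)
  invisible(path)
}
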