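#' Cohort schema: one row per operated patient
#'
#' The cohort table has one row per operation with demographics, operative
#' variables, coded comorbidities, in-hospital complications and linked
#' follow-up. All user-facing functions in the package take this table (a
#' plain data frame / tibble) as their first argument.
#'
#' @format Columns, types and units:
#' \describe{
#'   \item{patient_id}{opaque character identifier, unique}
#'   \item{age_at_op}{age at operation in years (numeric, >= 0)}
#'   \item{sex}{`"male"` or `"female"`}
#'   \item{op_date}{operation date, ISO-8601}
#'   \item{procedure}{`"AVR"` (isolated) or `"AVR_CABG"` (with concomitant
#'     coronary grafting)}
#'   \item{urgency}{`"elective"`, `"urgent"`, `"emergent"` or `"salvage"`}
#'   \item{multiple_valve, other_major_nonvalve_op, previous_avr}{logical
#'     exclusion flags}
#'   \item{euroscore}{additive EuroSCORE (numeric, >= 0)}
#'   \item{lvef_percent}{left-ventricular ejection fraction, 0-100, may be
#'     missing}
#'   \item{serum_creatinine}{baseline creatinine in umol/L, > 0, may be
#'     missing}
#'   \item{lung_disease, diabetes_treated, hypertension_treated,
#'     arrhythmia_preop, arteriopathy_extracardiac}{logical comorbidity flags}
#'   \item{smoker}{`"never"`, `"former"` or `"current"`}
#'   \item{complication_reop_bleeding, complication_stroke,
#'     complication_haemofiltration}{logical postoperative complication flags}
#'   \item{early_death}{logical: in-hospital or <= 30-day death (implies
#'     `event == 1`)}
#'   \item{followup_years}{observed follow-up in years (numeric, >= 0)}
#'   \item{event}{1 = died, 0 = censored}
#' }
#' @name cohort-schema
NULL

cohort_enums <- list(
  sex = c("male", "female"),
  procedure = c("AVR", "AVR_CABG"),
  urgency = c("elective", "urgent", "emergent", "salvage"),
  smoker = c("never", "former", "current")
)

cohort_flag_cols <- c(
  "multiple_valve", "other_major_nonvalve_op", "previous_avr",
  "lung_disease", "diabetes_treated", "hypertension_treated",
  "arrhythmia_preop", "arteriopathy_extracardiac",
  "complication_reop_bleeding", "complication_stroke",
  "complication_haemofiltration", "early_death"
)

cohort_columns <- function() {
  c("patient_id", "age_at_op", "sex", "op_date", "procedure", "urgency",
    "multiple_valve", "other_major_nonvalve_op", "previous_avr",
    "euroscore", "lvef_percent", "serum_creatinine",
    "lung_disease", "diabetes_treated", "hypertension_treated", "smoker",
    "arrhythmia_preop", "arteriopathy_extracardiac",
    "complication_reop_bleeding", "complication_stroke",
    "complication_haemofiltration", "early_death",
    "followup_years", "event")
}

cohort_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    age_at_op = readr::col_double(),
    sex = readr::col_character(),
    op_date = readr::col_date(format = "%Y-%m-%d"),
    procedure = readr::col_character(),
    urgency = readr::col_character(),
    euroscore = readr::col_double(),
    lvef_percent = readr::col_double(),
    serum_creatinine = readr::col_double(),
    smoker = readr::col_character(),
    followup_years = readr::col_double(),
    event = readr::col_integer(),
    .default = readr::col_logical()
  )
}

#' Read a patient cohort from CSV
#'
#' Reads a cohort CSV in the published schema (see [cohort-schema]),
#' validating column presence, enum tokens and row-level invariants. Rows
#' that fail validation are reported with their row number and offending
#' value; nothing is silently coerced.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row,
#'   ISO-8601 dates, lowercase enum tokens and empty cells for missing
#'   numeric values.
#' @param schema_version Schema identifier; only `"1"` is currently defined.
#' @return A tibble, one row per patient record, in schema column order.
#' @export
load_cohort <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    abort(paste0("Unknown cohort schema version: ", schema_version))
  }
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing <- setdiff(cohort_columns(), hdr)
  if (length(missing) > 0) {
    abort(paste0("Cohort schema error: missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- readr::read_csv(path, col_types = cohort_col_types(),
                       show_col_types = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    abort(paste0(
      "Cohort parse error in ", nrow(prob), " cell(s); first: row ",
      prob$row[1], ", expected ", prob$expected[1], ", got '",
      prob$actual[1], "'"))
  }
  x <- dplyr::select(x, dplyr::all_of(cohort_columns()))
  validate_cohort(x)
  x
}

#' Validate a cohort table against the schema invariants
#'
#' Checks enum tokens, value domains and cross-field invariants
#' (`followup_years >= 0`, `event` in \{0, 1\}, `early_death` implies
#' `event == 1`, LVEF in \[0, 100\], non-negative age / EuroSCORE /
#' creatinine, unique `patient_id`). Errors name the first offending row,
#' field and value.
#'
#' @param data A cohort table.
#' @return `data`, invisibly, when valid.
#' @export
validate_cohort <- function(data) {
  row_fail <- function(ok, field, vals) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      abort(paste0("Cohort invariant violation: row ", bad[1], ", field '",
                   field, "', value '", vals[bad[1]], "'"))
    }
  }
  for (f in names(cohort_enums)) {
    v <- data[[f]]
    row_fail(is.na(v) | v %in% cohort_enums[[f]], f, v)
  }
  row_fail(!is.na(data$patient_id) & !duplicated(data$patient_id),
           "patient_id", data$patient_id)
  row_fail(is.na(data$age_at_op) | data$age_at_op >= 0,
           "age_at_op", data$age_at_op)
  row_fail(is.na(data$euroscore) | data$euroscore >= 0,
           "euroscore", data$euroscore)
  row_fail(is.na(data$serum_creatinine) | data$serum_creatinine > 0,
           "serum_creatinine", data$serum_creatinine)
  row_fail(is.na(data$lvef_percent) |
             (data$lvef_percent >= 0 & data$lvef_percent <= 100),
           "lvef_percent", data$lvef_percent)
  row_fail(!is.na(data$followup_years) & data$followup_years >= 0,
           "followup_years", data$followup_years)
  row_fail(!is.na(data$event) & data$event %in% c(0L, 1L),
           "event", data$event)
  ed <- !is.na(data$early_death) & data$early_death
  row_fail(!ed | data$event == 1L, "early_death", data$early_death)
  invisible(data)
}

#' Write a cohort table to CSV in the published schema
#'
#' @param data A cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(dplyr::select(data, dplyr::all_of(cohort_columns())),
                   path, na = "")
  invisible(path)
}

exclusion_rules <- function() {
  # Fixed assessment order: a row failing several rules is tallied under the
  # first one only, so the tally is deterministic.
  list(
    "age<65" = function(d) d$age_at_op < 65,
    "urgency" = function(d) !(d$urgency %in% c("elective", "urgent")),
    "multiple_valve" = function(d) d$multiple_valve,
    "other_major_nonvalve_op" = function(d) d$other_major_nonvalve_op,
    "previous_avr" = function(d) d$previous_avr
  )
}

#' Apply the study inclusion/exclusion filters
#'
#' Retains elective or urgent first-time isolated AVR or AVR+CABG operations
#' in patients aged 65 or over: rows are excluded if age_at_op < 65, urgency
#' is emergent/salvage, the operation involved multiple valves or another
#' major non-valve procedure, or the patient had a previous AVR. Exclusion
#' reasons are assessed in that fixed order and each excluded row is tallied
#' under its first matching reason; the tally is attached as the
#' `"exclusion_tally"` attribute (see [exclusion_tally()]).
#'
#' Filtering is idempotent and retained + excluded counts always equal the
#' input row count.
#'
#' @param data A cohort table.
#' @return The filtered tibble with an `"exclusion_tally"` attribute.
#' @export
apply_inclusion_filters <- function(data) {
  rules <- exclusion_rules()
  reason <- rep(NA_character_, nrow(data))
  for (nm in names(rules)) {
    hit <- rules[[nm]](data)
    hit[is.na(hit)] <- FALSE
    reason[is.na(reason) & hit] <- nm
  }
  kept <- dplyr::as_tibble(data[is.na(reason), , drop = FALSE])
  counts <- vapply(names(rules),
                   function(nm) sum(reason == nm, na.rm = TRUE),
                   integer(1), USE.NAMES = FALSE)
  tally <- tibble::tibble(reason = names(rules), count = counts)
  attr(kept, "exclusion_tally") <- tally
  kept
}

#' Exclusion tally of a filtered cohort
#'
#' @param data A cohort returned by [apply_inclusion_filters()].
#' @return A two-column tibble (`reason`, `count`), one row per exclusion
#'   rule in assessment order.
#' @export
exclusion_tally <- function(data) {
  t <- attr(data, "exclusion_tally")
  if (is.null(t)) {
    abort("No exclusion tally: was the cohort filtered with apply_inclusion_filters()?")
  }
  t
}

#' Write an exclusion tally to CSV
#'
#' @param data A filtered cohort or a tally tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_tally <- function(data, path) {
  t <- if (is.data.frame(data) && all(c("reason", "count") %in% names(data))) {
    data
  } else {
    exclusion_tally(data)
  }
  readr::write_csv(t, path)
  invisible(path)
}

#' Derive coded covariates from raw cohort fields
#'
#' Appends the deterministic covariate codings used throughout the analyses:
#' \describe{
#'   \item{lvf_class}{left-ventricular function from LVEF: `normal` (>= 52),
#'     `mild` (41-51), `moderate` (30-40), `severe` (< 30); missing LVEF
#'     stays missing}
#'   \item{ckd}{chronic kidney disease: serum creatinine >= 200 umol/L}
#'   \item{age_group}{`65-69` = \[65, 70), `70-79` = \[70, 80), `>=80` =
#'     \[80, Inf)}
#'   \item{euroscore_class}{`high` iff additive EuroSCORE > `euroscore_cut`}
#'   \item{procedure_group}{factor copy of `procedure`}
#'   \item{any_complication}{OR of reoperation-for-bleeding, stroke and
#'     haemofiltration flags}
#' }
#' Coding is a pure function of the row; missing LVEF or creatinine
#' propagates as missing and is never imputed.
#'
#' @param data A cohort table.
#' @param euroscore_cut Threshold above which EuroSCORE is coded `high`
#'   (default 5, i.e. high means > 5).
#' @return `data` with the coded columns appended.
#' @export
derive_covariates <- function(data, euroscore_cut = 5) {
  bad <- which(!is.na(data$lvef_percent) &
                 (data$lvef_percent < 0 | data$lvef_percent > 100))
  if (length(bad) > 0) {
    abort(paste0("LVEF outside [0,100] at row ", bad[1], ": ",
                 data$lvef_percent[bad[1]]))
  }
  lvf_levels <- c("normal", "mild", "moderate", "severe")
  dplyr::mutate(
    dplyr::as_tibble(data),
    lvf_class = factor(dplyr::case_when(
      is.na(.data$lvef_percent) ~ NA_character_,
      .data$lvef_percent >= 52 ~ "normal",
      .data$lvef_percent >= 41 ~ "mild",
      .data$lvef_percent >= 30 ~ "moderate",
      TRUE ~ "severe"
    ), levels = lvf_levels),
    ckd = .data$serum_creatinine >= 200,
    age_group = factor(dplyr::case_when(
      .data$age_at_op < 65 ~ NA_character_,
      .data$age_at_op < 70 ~ "65-69",
      .data$age_at_op < 80 ~ "70-79",
      TRUE ~ ">=80"
    ), levels = c("65-69", "70-79", ">=80")),
    euroscore_class = factor(
      ifelse(is.na(.data$euroscore), NA_character_,
             ifelse(.data$euroscore > euroscore_cut, "high", "low")),
      levels = c("low", "high")),
    procedure_group = factor(.data$procedure, levels = cohort_enums$procedure),
    any_complication = .data$complication_reop_bleeding |
      .data$complication_stroke | .data$complication_haemofiltration
  )
}
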