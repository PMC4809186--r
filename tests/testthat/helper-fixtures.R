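# Fixture builders shared by the suite: everything is generated in code.

# One schema-complete patient row with overridable fields.
patient_row <- function(...) {
  row <- tibble::tibble(
    patient_id = "P1", age_at_op = 75, sex = "male",
    op_date = as.Date("2000-06-15"), procedure = "AVR",
    urgency = "elective", multiple_valve = FALSE,
    other_major_nonvalve_op = FALSE, previous_avr = FALSE,
    euroscore = 6, lvef_percent = 55, serum_creatinine = 90,
    lung_disease = FALSE, diabetes_treated = FALSE,
    hypertension_treated = FALSE, smoker = "never",
    arrhythmia_preop = FALSE, arteriopathy_extracardiac = FALSE,
    complication_reop_bleeding = FALSE, complication_stroke = FALSE,
    complication_haemofiltration = FALSE, early_death = FALSE,
    followup_years = 5, event = 0L)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# Bind several patient rows, auto-numbering ids; each argument is a list of
# field overrides.
make_cohort <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    do.call(patient_row, c(list(patient_id = paste0("P", i)), rows[[i]]))
  }))
  out
}

# Rectangular life table with constant annual death probability q.
flat_lifetable <- function(q, ages = 60:110, years = 1990:2020,
                           sexes = c("male", "female")) {
  grid <- expand.grid(age = ages, sex = sexes, year = years,
                      stringsAsFactors = FALSE)
  grid$qx <- q
  lifetable(grid)
}

# Life table where q depends on (age, sex, year) through a supplied function.
fun_lifetable <- function(f, ages = 60:110, years = 1990:2020,
                          sexes = c("male", "female")) {
  grid <- expand.grid(age = ages, sex = sexes, year = years,
                      stringsAsFactors = FALSE)
  grid$qx <- mapply(f, grid$age, grid$sex, grid$year)
  lifetable(grid)
}

# Null-excess synthetic config: survival driven by the life table alone.
null_config <- function(n, seed, ...) {
  args <- list(n_patients = n, seed = seed,
               baseline_excess_hazard = 0, early_death_base_prob = 0,
               loss_to_followup_prob = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

write_temp_csv <- function(data, dir = tempdir()) {
  path <- tempfile(fileext = ".csv", tmpdir = dir)
  readr::write_csv(data, path, na = "")
  path
}

# Textbook product-limit loop (independent oracle for km_estimate).
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  tibble::tibble(time = ut, surv = out)
}
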