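#' Assemble an end-to-end run configuration
#'
#' Collects everything one analysis run needs: the input mode (a cohort CSV
#' or the synthetic generator), the life table, the Monte Carlo settings,
#' the stratifications and restriction horizons, the model specifications
#' and a single global seed from which every stage's sub-seed is derived
#' (so e.g. changing the MC run count never perturbs the synthetic cohort).
#'
#' @param input_mode `"synthetic"` or `"real_csv"`.
#' @param cohort_path Cohort CSV (for `"real_csv"`).
#' @param lifetable_path Life-table CSV; when `NULL` in synthetic mode a
#'   default Gompertz table from [generate_lifetable()] is used.
#' @param synthetic An [synthetic_config()] (synthetic mode).
#' @param mc An [mc_config()].
#' @param strata List of character vectors of coded-covariate columns
#'   defining the median-survival stratifications.
#' @param horizons List of restriction horizons tau in years; `NULL`
#'   entries mean the entire follow-up period.
#' @param compare_mode Reference-comparison mode, see
#'   [restricted_reference_compare()].
#' @param logistic_predictors,cox_predictors Predictor sets for the
#'   early-mortality and long-term models.
#' @param alpha_out Backward-elimination stay threshold.
#' @param screen_alpha Family-wise level for the Bonferroni screen.
#' @param seed Global integer seed.
#' @return An `avr_run_config` list.
#' @export
run_config <- function(input_mode = c("synthetic", "real_csv"),
                       cohort_path = NULL, lifetable_path = NULL,
                       synthetic = synthetic_config(),
                       mc = mc_config(),
                       strata = list("procedure_group",
                                     c("procedure_group", "age_group"),
                                     c("procedure_group", "euroscore_class"),
                                     c("procedure_group", "any_complication")),
                       horizons = list(8, NULL),
                       compare_mode = "pooled",
                       logistic_predictors = c("euroscore_class", "sex",
                                               "procedure_group"),
                       cox_predictors = default_predictors(),
                       alpha_out = 0.05, screen_alpha = 0.05,
                       seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "real_csv" && is.null(cohort_path)) {
    abort("real_csv mode requires cohort_path")
  }
  bad_tau <- vapply(horizons, function(h) !is.null(h) && h <= 0, logical(1))
  if (any(bad_tau)) abort("Restriction horizons must be positive")
  seed <- as.integer(seed)
  # stage sub-seeds derived from the single global seed
  synthetic$seed <- derive_seed(seed, "synthetic_cohort")
  mc$seed <- derive_seed(seed, "mc_reference")
  structure(list(
    input_mode = input_mode, cohort_path = cohort_path,
    lifetable_path = lifetable_path, synthetic = synthetic, mc = mc,
    strata = strata, horizons = horizons, compare_mode = compare_mode,
    logistic_predictors = logistic_predictors,
    cox_predictors = cox_predictors,
    alpha_out = alpha_out, screen_alpha = screen_alpha, seed = seed),
    class = "avr_run_config")
}

#' Median survival by stratum
#'
#' Per-stratum patient counts and Kaplan-Meier median survival with
#' Brookmeyer-Crowley confidence limits, for each requested stratification.
#' Every combination of the stratifying factor levels appears; an empty
#' stratum gets `n = 0` and undefined estimates rather than aborting. Open
#' upper bounds render as an ellipsis in the `label` column.
#'
#' @param data A covariate-coded cohort table.
#' @param strata List of character vectors of stratifying columns.
#' @return A tibble: `stratification`, stratum values (collapsed into
#'   `stratum`), `n`, `events`, `median`, `ci_lower`, `ci_upper`, `label`.
#' @export
summarize_strata <- function(data,
                             strata = list("procedure_group",
                                           c("procedure_group", "age_group"))) {
  rows <- lapply(strata, function(vars) {
    levs <- lapply(vars, function(v) {
      x <- data[[v]]
      if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
    })
    combos <- expand.grid(rev(levs), stringsAsFactors = FALSE)[
      , rev(seq_along(vars)), drop = FALSE]
    names(combos) <- vars
    out <- lapply(seq_len(nrow(combos)), function(i) {
      sel <- rep(TRUE, nrow(data))
      for (v in vars) {
        sel <- sel & !is.na(data[[v]]) &
          as.character(data[[v]]) == as.character(combos[i, v])
      }
      sub <- data[sel, , drop = FALSE]
      stratum <- paste(vapply(vars, function(v)
        paste0(v, "=", combos[i, v]), character(1)), collapse = "; ")
      if (nrow(sub) == 0) {
        return(tibble::tibble(
          stratification = paste(vars, collapse = " x "), stratum = stratum,
          n = 0L, events = 0L, median = NA_real_, ci_lower = NA_real_,
          ci_upper = NA_real_, label = "…"))
      }
      med <- median_survival(km_estimate(sub))
      tibble::tibble(
        stratification = paste(vars, collapse = " x "), stratum = stratum,
        n = nrow(sub), events = as.integer(sum(sub$event)),
        median = med$median, ci_lower = med$ci_lower,
        ci_upper = med$ci_upper, label = format_median(med))
    })
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or generate the cohort and life table; apply the
#' inclusion filters; code covariates; Kaplan-Meier curves overall and by
#' procedure; median survival by stratum; Monte Carlo matched-population
#' reference; restricted comparisons per horizon, overall and per sex;
#' logistic and Cox models with backward elimination; Bonferroni univariate
#' screen; proportional-hazards diagnostics. Any stage failure aborts with
#' the stage name and cause.
#'
#' @param cfg An [run_config()].
#' @return An `avr_report` list of result tables plus a `manifest`
#'   sufficient to reproduce the bundle byte-identically.
#' @export
run_pipeline <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  lt <- stage("lifetable", {
    if (!is.null(cfg$lifetable_path)) load_lifetable(cfg$lifetable_path)
    else generate_lifetable()
  })

  raw <- stage("load", {
    if (cfg$input_mode == "synthetic") {
      gen <- generate_cohort(cfg$synthetic, lt)
      gen$cohort
    } else {
      load_cohort(cfg$cohort_path)
    }
  })

  cohort <- stage("filter", apply_inclusion_filters(raw))
  tally <- exclusion_tally(cohort)
  cohort <- stage("code_covariates", derive_covariates(cohort))
  lost <- sum(cohort$event == 0 &
                cohort$followup_years <
                years_between(cohort$op_date,
                              attr(raw, "admin_censor_date") %||%
                                max(cohort$op_date)) - 1e-9)

  km_overall <- stage("km", km_estimate(cohort))
  km_by_proc <- stage("km", {
    lapply(split(cohort, cohort$procedure_group), km_estimate)
  })
  descriptive <- stage("descriptive",
                       group_compare_descriptive(cohort, "procedure_group"))
  medians <- stage("medians", summarize_strata(cohort, cfg$strata))

  reference <- stage("mc_reference",
                     simulate_reference_cohort(lt, cohort, cfg$mc))
  ref_curve <- stage("mc_reference", reference_km(reference))

  comparisons <- stage("compare", {
    strata_sets <- list(all = rep(TRUE, nrow(cohort)),
                        male = cohort$sex == "male",
                        female = cohort$sex == "female")
    rows <- list()
    for (s in names(strata_sets)) {
      sel <- strata_sets[[s]]
      ref_sel <- reference$source_patient_id %in% cohort$patient_id[sel]
      for (tau in cfg$horizons) {
        lr <- restricted_reference_compare(
          cohort[sel, , drop = FALSE], reference[ref_sel, , drop = FALSE],
          tau = tau, mode = cfg$compare_mode)
        rows[[length(rows) + 1]] <- dplyr::mutate(
          dplyr::as_tibble(lr), stratum = s, .before = 1)
      }
    }
    dplyr::bind_rows(rows)
  })

  logistic <- stage("logistic", backward_eliminate(
    cohort, cfg$logistic_predictors, fitter = "logistic",
    alpha_out = cfg$alpha_out, outcome = "early_death"))
  cox <- stage("cox", backward_eliminate(
    cohort, cfg$cox_predictors, fitter = "cox",
    alpha_out = cfg$alpha_out))
  screen <- stage("screen", univariate_screen(
    cohort, cfg$cox_predictors, alpha = cfg$screen_alpha, fitter = "cox"))
  ph <- stage("ph_diagnostic", {
    if (length(cox$predictors) > 0) ph_diagnostic(cox) else NULL
  })

  manifest <- list(
    package = "avrsurv",
    version = as.character(utils::packageVersion("avrsurv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = hash31(paste(deparse(unclass(cfg)), collapse = "")),
    n_raw = nrow(raw), n_included = nrow(cohort),
    n_lost_to_followup = lost)

  structure(list(
    lifetable = lt, cohort = cohort, exclusion_tally = tally,
    descriptive = descriptive, medians = medians,
    km_overall = km_overall, km_by_procedure = km_by_proc,
    reference = reference, reference_curve = ref_curve,
    comparisons = comparisons, logistic = logistic, cox = cox,
    screen = screen, ph = ph, manifest = manifest),
    class = "avr_report")
}

#' Write a report bundle to a directory of CSV/JSON files
#'
#' Plain-text outputs only: descriptive table, exclusion tally, median
#' table, curves, comparison and regression tables, elimination traces and
#' the JSON manifest.
#'
#' @param bundle An `avr_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(bundle$exclusion_tally, p("exclusion_tally.csv"))
  readr::write_csv(bundle$descriptive, p("descriptive.csv"))
  readr::write_csv(bundle$medians, p("median_survival.csv"))
  write_curve(bundle$km_overall, p("km_overall.csv"))
  for (g in names(bundle$km_by_procedure)) {
    write_curve(bundle$km_by_procedure[[g]],
                p(paste0("km_", g, ".csv")))
  }
  write_curve(bundle$reference_curve, p("reference_km.csv"))
  readr::write_csv(bundle$comparisons, p("reference_comparisons.csv"))
  readr::write_csv(tidy(bundle$logistic), p("logistic_model.csv"))
  readr::write_csv(bundle$logistic$elimination_trace,
                   p("logistic_elimination_trace.csv"))
  readr::write_csv(tidy(bundle$cox), p("cox_model.csv"))
  readr::write_csv(bundle$cox$elimination_trace,
                   p("cox_elimination_trace.csv"))
  readr::write_csv(dplyr::as_tibble(bundle$screen), p("univariate_screen.csv"))
  if (!is.null(bundle$ph)) {
    readr::write_csv(bundle$ph$table, p("ph_diagnostic.csv"))
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
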