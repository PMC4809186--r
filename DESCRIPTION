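Package: avrsurv
Title: Long-Term Survival Analysis for Elderly Aortic Valve Replacement
    Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking long-term survival after surgical
    aortic valve replacement (AVR) in elderly patients against the
    matched general population. Provides cohort schema validation,
    inclusion filtering and covariate coding for surgical registries;
    period life-table handling with a closed-form (Ederer-I style)
    expected-survival curve; a Monte Carlo engine that simulates an
    operation-year-, age- and sex-matched population counterpart for
    every patient and aggregates the runs into a reference Kaplan-Meier
    curve; Kaplan-Meier, median-survival and (weighted) log-rank
    machinery including horizon-restricted comparisons against the
    reference; logistic and Cox risk models with stepwise backward
    elimination, Bonferroni-screened univariate analysis and
    proportional-hazards diagnostics; and a synthetic-data module that
    generates registry-like cohorts with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
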