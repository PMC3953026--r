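Package: telotrack
Title: Leukocyte Telomere Length Quantification and Longitudinal Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for monochrome multiplex qPCR telomere
    length measurement and its downstream epidemiology. Converts raw well-level
    Ct values into absolute leukocyte telomere lengths via replicate quality
    control, plate normalization against a K562 calibrator, and the delta-delta-Ct
    calculation anchored at 5,290 basepairs; computes exact-time 10-year telomere
    length change, inter-examination age recalibration, examination-specific
    quartiles, and quartile-median regression dilution ratios; and fits
    cross-sectional quartile trend tests, change-predictor regressions with
    age/sex imputation of missing covariates, ICD-8/ICD-10 registry endpoint
    extraction, and proportional-hazards quartile models. A synthetic-cohort
    generator emulates plate files, two-examination cohort tables, and registry
    event tables so the whole pipeline runs and can be validated without access
    to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    survival,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
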