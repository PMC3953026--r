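#' Read and write the pipeline's CSV dialects
#'
#' One row per well / per exam record / per registry event, ISO-8601 dates,
#' UTF-8 with a header.
#'
#' @param path File path.
#' @return A tibble ([read_plates()], [read_exams()], [read_registry()]).
#' @name telo_io
NULL

#' @rdname telo_io
#' @export
read_plates <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      sample_id = readr::col_character(),
      role = readr::col_character(),
      assay = readr::col_character(),
      ct = readr::col_double(),
      primer_dimer = readr::col_logical()
    )
  )
}

#' @rdname telo_io
#' @export
read_exams <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    exam_id = readr::col_character(),
    exam_date = readr::col_date(),
    sex = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' @rdname telo_io
#' @export
read_registry <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    event_date = readr::col_date(),
    event_type = readr::col_character(),
    icd_version = readr::col_character(),
    icd_code = readr::col_character()
  ))
}

#' Validate pipeline input tables
#'
#' Schema and invariant checks for the three input tables; hard failures
#' (violations of type contracts) are distinguished from warnings
#' (implausible but usable values, e.g. an exam gap far from the expected
#' decade).
#'
#' @param wells,exam1,exam2,registry Any subset of the pipeline inputs
#'   (`NULL` to skip).
#' @return Tibble of findings: `table`, `check`, `severity`
#'   (`"failure"`/`"warning"`), `n_offending`, `message`.
#' @export
validate_inputs <- function(wells = NULL, exam1 = NULL, exam2 = NULL,
                            registry = NULL) {
  findings <- list()
  note <- function(table, check, severity, n, msg) {
    findings[[length(findings) + 1]] <<- tibble(
      table = table, check = check, severity = severity,
      n_offending = n, message = msg
    )
  }

  if (!is.null(wells)) {
    miss <- setdiff(
      c("plate_id", "sample_id", "role", "assay", "ct", "primer_dimer"),
      names(wells)
    )
    if (length(miss)) {
      note("wells", "schema", "failure", length(miss),
        paste("missing columns:", paste(miss, collapse = ", ")))
    } else {
      bad_ct <- sum(!is.finite(wells$ct) | wells$ct <= 0)
      if (bad_ct) note("wells", "ct_positive", "failure", bad_ct,
        "Ct values must be finite and positive")
      bad_role <- sum(!wells$role %in% c("participant", "calibrator", "internal_control"))
      if (bad_role) note("wells", "role_enum", "failure", bad_role,
        "unknown role values")
      bad_assay <- sum(!wells$assay %in% c("telomere", "albumin"))
      if (bad_assay) note("wells", "assay_enum", "failure", bad_assay,
        "unknown assay values")
    }
  }

  for (nm in c("exam1", "exam2")) {
    ex <- get(nm)
    if (is.null(ex)) next
    if (!all(c("participant_id", "exam_date", "age", "tl_bp") %in% names(ex))) {
      note(nm, "schema", "failure", 1L, "missing required exam columns")
      next
    }
    bad_tl <- sum(!is.na(ex$tl_bp) & ex$tl_bp <= 0)
    if (bad_tl) note(nm, "tl_positive", "failure", bad_tl, "tl_bp must be > 0")
    bad_age <- sum(!is.na(ex$age) & ex$age <= 0)
    if (bad_age) note(nm, "age_positive", "failure", bad_age, "age must be > 0")
    if (all(c("weight_kg", "height_m", "bmi") %in% names(ex))) {
      ok <- complete.cases(ex[, c("weight_kg", "height_m", "bmi")])
      bad_bmi <- sum(abs(ex$bmi[ok] - ex$weight_kg[ok] / ex$height_m[ok]^2) > 0.1)
      if (bad_bmi) note(nm, "bmi_consistency", "warning", bad_bmi,
        "bmi differs from weight/height^2")
    }
  }

  if (!is.null(exam1) && !is.null(exam2)) {
    j <- inner_join(
      select(exam1, "participant_id", d1 = "exam_date"),
      select(exam2, "participant_id", d2 = "exam_date"),
      by = "participant_id"
    )
    gap <- as.numeric(as.Date(j$d2) - as.Date(j$d1)) / 365.25
    if (any(gap <= 0)) note("exams", "gap_positive", "failure", sum(gap <= 0),
      "exam 2 must postdate exam 1")
    odd <- sum(gap > 0 & (gap < 5 | gap > 15))
    if (odd) note("exams", "gap_plausible", "warning", odd,
      "inter-exam gap far from the expected ~9-10 years")
  }

  if (!is.null(registry)) {
    if (!all(c("participant_id", "event_date", "event_type") %in% names(registry))) {
      note("registry", "schema", "failure", 1L, "missing required registry columns")
    } else {
      bad_type <- sum(!registry$event_type %in% c("diagnosis", "death", "emigration"))
      if (bad_type) note("registry", "type_enum", "failure", bad_type,
        "unknown event_type values")
      dg <- registry[registry$event_type == "diagnosis", ]
      no_code <- sum(is.na(dg$icd_code))
      if (no_code) note("registry", "diagnosis_code", "failure", no_code,
        "diagnosis events must carry an ICD code")
    }
  }

  if (!length(findings)) {
    return(tibble(
      table = character(), check = character(), severity = character(),
      n_offending = integer(), message = character()
    ))
  }
  dplyr::bind_rows(findings)
}

#' Run the full pipeline end to end
#'
#' Optionally simulates a synthetic study (cohort, plates, registry), then
#' quantifies the plates, builds the calibrated change table, and produces
#' the three report tables: quartile characteristics with trend tests,
#' change-predictor regressions, and per-endpoint quartile hazard ratios.
#' Reports are returned and, if `outdir` is given, written as CSV together
#' with a plain-text run log (seed, row counts per stage).
#'
#' @param config A [generator_config()] (used when simulating).
#' @param exam1,exam2,registry,wells Optional user-supplied tables; any that
#'   are `NULL` are simulated from `config`.
#' @param endpoints Endpoints to analyse (default all six).
#' @param calibrate_age Apply the exam-2 age recalibration (default TRUE).
#' @param adjust Covariates for the multivariable Cox models.
#' @param outdir Optional output directory for CSV reports and the run log.
#' @return List of class `telo_report`: `change`, `change_summary`,
#'   `characteristics` (per exam), `predictors` (uni+multivariable),
#'   `cox` (per endpoint), `validation`, `log`.
#' @export
run_pipeline <- function(config = generator_config(),
                         exam1 = NULL, exam2 = NULL, registry = NULL,
                         wells = NULL,
                         endpoints = c(
                           "all_cause_mortality", "cancer", "copd",
                           "dm2", "icvd", "ihd"
                         ),
                         calibrate_age = TRUE,
                         adjust = c("age", "sex"),
                         outdir = NULL) {
  if (!inherits(config, "telo_generator_config")) {
    config <- do.call(generator_config, config)
  }
  log_lines <- c(
    sprintf("telotrack pipeline; seed %d", config$seed),
    sprintf("n_participants %d", config$n_participants)
  )
  simulated <- is.null(exam1) || is.null(exam2)
  if (simulated) {
    cohort <- generate_cohort(config)
    exam1 <- cohort$exam1
    exam2 <- cohort$exam2
    if (is.null(registry)) {
      registry <- simulate_registry(cohort$truth, exam2, config, exam1 = exam1)
    }
    log_lines <- c(log_lines, "inputs: simulated")
  }

  validation <- validate_inputs(
    wells = wells, exam1 = exam1, exam2 = exam2, registry = registry
  )
  if (any(validation$severity == "failure")) {
    abort(paste(
      "input validation failed:",
      paste(validation$message[validation$severity == "failure"], collapse = "; ")
    ))
  }

  if (!is.null(wells)) {
    quant <- quantify_plate_set(wells)
    log_lines <- c(log_lines, sprintf("quantified %d samples", nrow(quant$results)))
  } else {
    quant <- NULL
  }

  change <- build_change_table(exam1, exam2, calibrate_age = calibrate_age)
  log_lines <- c(log_lines, sprintf("change table: %d participants", nrow(change)))

  characteristics <- list(
    exam1 = quartile_characteristics(impute_covariates(exam1)),
    exam2 = quartile_characteristics(impute_covariates(exam2))
  )

  design <- change_predictor_table(exam1, exam2, change)
  predictors <- list(
    univariable = fit_change_predictors(design, mode = "univariable"),
    multivariable = fit_change_predictors(design, mode = "multivariable")
  )

  base <- exam2 |>
    select("participant_id", entry_date = "exam_date", "age", "sex") |>
    inner_join(select(change, "participant_id", quartile = "change_quartile"),
      by = "participant_id"
    )
  cox <- purrr::map(setNames(endpoints, endpoints), function(ep) {
    fu <- build_followup(base, registry, endpoint_definition(ep))
    fit_cox_quartiles(fu, adjust = adjust)
  })
  log_lines <- c(
    log_lines,
    purrr::imap_chr(cox, ~ sprintf(
      "%s: %d included, %d events, trend p %.3g",
      .y, sum(.x$table$n), sum(.x$table$events), .x$trend_p
    ))
  )

  report <- structure(
    list(
      change = change,
      change_summary = change_summary(change),
      characteristics = characteristics,
      predictors = predictors,
      cox = cox,
      quant = quant,
      validation = validation,
      log = log_lines,
      config = config
    ),
    class = "telo_report"
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(change, file.path(outdir, "change.csv"))
    readr::write_csv(characteristics$exam1, file.path(outdir, "characteristics_exam1.csv"))
    readr::write_csv(characteristics$exam2, file.path(outdir, "characteristics_exam2.csv"))
    readr::write_csv(
      dplyr::bind_rows(
        tidy(predictors$univariable), tidy(predictors$multivariable)
      ),
      file.path(outdir, "change_predictors.csv")
    )
    readr::write_csv(
      purrr::imap_dfr(cox, ~ mutate(tidy(.x), endpoint = .y, trend_p = .x$trend_p)),
      file.path(outdir, "cox_quartiles.csv")
    )
    if (!is.null(quant)) {
      readr::write_csv(tidy(quant), file.path(outdir, "quantification.csv"))
    }
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  report
}

#' @export
print.telo_report <- function(x, ...) {
  cat("<telo_report>\n")
  writeLines(paste(" ", x$log))
  invisible(x)
}
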