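icd10_pools <- list(
  cancer = c("C18", "C34", "C50", "C61", "C44", "C67", "C16", "C25", "D05", "D09"),
  copd = c("J41", "J42", "J43", "J44"),
  dm2 = c("E10", "E11", "E14"),
  icvd = c("I61", "I63", "I64", "I65", "I66", "G45"),
  ihd = c("I20", "I21", "I24", "I25")
)
icd8_pools <- list(
  copd = c("491", "492"),
  dm2 = c("249", "250"),
  icvd = c("431", "433", "434", "436", "437", "438"),
  ihd = c("410", "411", "412", "413", "414")
)

#' Simulate a registry of dated diagnosis, death, and emigration events
#'
#' Death times are drawn from a Gompertz-type hazard whose log is linear in
#' age at exam 2 and in *shorter* true telomere length (per kbp); disease
#' events for cancer, COPD, type-2 diabetes, ischemic cerebrovascular
#' disease, and ischemic heart disease are drawn as dated diagnoses carrying
#' concrete ICD-8 or ICD-10 codes from the endpoint code sets (ICD-8 for
#' events before 1994, except cancer which the cancer registry codes in
#' ICD-10 throughout); a small fraction of participants emigrate during
#' follow-up. Disease onset clocks start 15 years before exam 1, so a
#' realistic share of diagnoses is prevalent by the exam-2 baseline and
#' exercises the exclusion rule in [build_followup()].
#'
#' @param truth Truth table from [generate_cohort()] (per-participant true
#'   exam-2 telomere length).
#' @param exam2 Exam-2 table (entry dates and ages).
#' @param config The [generator_config()] used for the cohort.
#' @param exam1 Optional exam-1 table (used for disease onset clocks;
#'   defaults to exam-2 dates minus the gap).
#' @return Tibble of registry events: `participant_id`, `event_date`,
#'   `event_type` (`diagnosis`/`death`/`emigration`), `icd_version`,
#'   `icd_code`.
#' @export
simulate_registry <- function(truth, exam2, config = generator_config(),
                              exam1 = NULL) {
  if (!inherits(config, "telo_generator_config")) {
    config <- do.call(generator_config, config)
  }
  set.seed(config$seed + 1L)
  n <- nrow(exam2)
  stopifnot(nrow(truth) == n)
  truth <- truth[match(exam2$participant_id, truth$participant_id), ]

  registry_end <- as.Date("2011-06-07")
  gomp_g <- 0.09 # hazard doubling roughly every 8 years of follow-up

  # --- deaths ------------------------------------------------------------
  lam <- config$mortality_baseline_hazard * exp(
    config$mortality_age_log_hr * (exam2$age - 70) +
      config$mortality_tl_log_hr_per_kbp * (4.4 - truth$true_tl_exam2_bp / 1000)
  )
  e <- rexp(n)
  t_death <- log1p(gomp_g * e / lam) / gomp_g
  death_date <- exam2$exam_date + round(t_death * 365.25)
  deaths <- tibble(
    participant_id = exam2$participant_id,
    event_date = death_date,
    event_type = "death",
    icd_version = NA_character_,
    icd_code = NA_character_
  ) |>
    dplyr::filter(.data$event_date <= registry_end)

  # --- disease diagnoses -------------------------------------------------
  onset_start <- if (!is.null(exam1)) {
    exam1$exam_date[match(exam2$participant_id, exam1$participant_id)] - round(15 * 365.25)
  } else {
    exam2$exam_date - round((truth$gap_years + 15) * 365.25)
  }
  icd10_switch <- as.Date("1994-01-01")

  diseases <- purrr::imap_dfr(config$morbidity_rates, function(rate, ep) {
    t_ev <- rexp(n, rate = rate)
    ev_date <- onset_start + round(t_ev * 365.25)
    end <- if (ep == "cancer") as.Date("2009-12-31") else as.Date("2011-05-10")
    keep <- ev_date <= end
    if (!any(keep)) return(tibble())
    ev_date <- ev_date[keep]
    use_icd8 <- ep != "cancer" & ev_date < icd10_switch & ep %in% names(icd8_pools)
    code <- character(sum(keep))
    code[use_icd8] <- sample(icd8_pools[[ep]], sum(use_icd8), replace = TRUE)
    code[!use_icd8] <- sample(icd10_pools[[ep]], sum(!use_icd8), replace = TRUE)
    tibble(
      participant_id = exam2$participant_id[keep],
      event_date = ev_date,
      event_type = "diagnosis",
      icd_version = if_else(use_icd8, "ICD8", "ICD10"),
      icd_code = code
    )
  })

  # --- emigration --------------------------------------------------------
  n_emi <- round(config$emigration_fraction * n)
  emigrations <- if (n_emi > 0) {
    who <- sample.int(n, n_emi)
    tibble(
      participant_id = exam2$participant_id[who],
      event_date = exam2$exam_date[who] +
        round(runif(n_emi, 30, as.numeric(registry_end - max(exam2$exam_date)))),
      event_type = "emigration",
      icd_version = NA_character_,
      icd_code = NA_character_
    )
  } else {
    tibble()
  }

  dplyr::bind_rows(deaths, diseases, emigrations) |>
    arrange(.data$participant_id, .data$event_date)
}
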