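#' Endpoint definitions: ICD code sets and registry censor dates
#'
#' The six prospective endpoints with their inclusive ICD-8 / ICD-10
#' category ranges and registry end dates: all-cause mortality (no codes,
#' censored 2011-06-07), cancer (ICD-10 C00-D09, censored 2009-12-31), and
#' COPD (ICD-8 491-492, ICD-10 J41-J44), type-2 diabetes (249-250,
#' E10-E14), ischemic cerebrovascular disease (431-438, I61-I66 and G45),
#' and ischemic heart disease (410-414, I20-I25), all censored 2011-05-10.
#'
#' @param name One of `"all_cause_mortality"`, `"cancer"`, `"copd"`,
#'   `"dm2"`, `"icvd"`, `"ihd"`.
#' @return List: `name`, `icd8_ranges` (list of integer pairs),
#'   `icd10_ranges` (list of 3-character category pairs), `censor_date`.
#' @export
endpoint_definition <- function(name = c(
                                  "all_cause_mortality", "cancer", "copd",
                                  "dm2", "icvd", "ihd"
                                )) {
  name <- match.arg(name)
  defs <- list(
    all_cause_mortality = list(
      icd8 = list(), icd10 = list(), censor = "2011-06-07"
    ),
    cancer = list(
      icd8 = list(), icd10 = list(c("C00", "D09")), censor = "2009-12-31"
    ),
    copd = list(
      icd8 = list(c(491L, 492L)), icd10 = list(c("J41", "J44")),
      censor = "2011-05-10"
    ),
    dm2 = list(
      icd8 = list(c(249L, 250L)), icd10 = list(c("E10", "E14")),
      censor = "2011-05-10"
    ),
    icvd = list(
      icd8 = list(c(431L, 438L)),
      icd10 = list(c("I61", "I66"), c("G45", "G45")),
      censor = "2011-05-10"
    ),
    ihd = list(
      icd8 = list(c(410L, 414L)), icd10 = list(c("I20", "I25")),
      censor = "2011-05-10"
    )
  )
  d <- defs[[name]]
  list(
    name = name,
    icd8_ranges = d$icd8,
    icd10_ranges = d$icd10,
    censor_date = as.Date(d$censor)
  )
}

# min() that stays quiet on the empty groups dplyr pre-evaluates
min_date <- function(x) {
  x <- as.Date(x)
  if (length(x) == 0) return(as.Date(NA)) else min(x)
}

# ordinal position of an ICD-10 3-character category, NA if unparseable
icd10_ordinal <- function(code) {
  code <- toupper(substr(trimws(code), 1, 3))
  ok <- grepl("^[A-Z][0-9]{2}$", code)
  out <- rep(NA_real_, length(code))
  out[ok] <- (match(substr(code[ok], 1, 1), LETTERS) - 1) * 100 +
    as.integer(substr(code[ok], 2, 3))
  out
}

icd8_category <- function(code) {
  code <- substr(trimws(as.character(code)), 1, 3)
  ok <- grepl("^[0-9]{3}$", code)
  out <- rep(NA_integer_, length(code))
  out[ok] <- as.integer(code[ok])
  out
}

#' Does an ICD code fall in an endpoint's code set?
#'
#' Matching uses the 3-character category only, so subcodes (e.g. `C50.9`)
#' inherit their category's membership; ranges are inclusive at both ends.
#'
#' @param icd_version `"ICD8"` or `"ICD10"` (vectorised).
#' @param icd_code Code strings.
#' @param definition An [endpoint_definition()].
#' @return Logical vector; `NA` where the code does not parse.
#' @export
icd_matches <- function(icd_version, icd_code, definition) {
  out <- rep(FALSE, length(icd_code))
  is8 <- icd_version == "ICD8"
  if (any(is8)) {
    cat8 <- icd8_category(icd_code[is8])
    m <- rep(FALSE, sum(is8))
    for (r in definition$icd8_ranges) m <- m | (cat8 >= r[1] & cat8 <= r[2])
    m[is.na(cat8)] <- NA
    out[is8] <- m
  }
  if (any(!is8)) {
    ord <- icd10_ordinal(icd_code[!is8])
    m <- rep(FALSE, sum(!is8))
    for (r in definition$icd10_ranges) {
      m <- m | (ord >= icd10_ordinal(r[1]) & ord <= icd10_ordinal(r[2]))
    }
    m[is.na(ord)] <- NA
    out[!is8] <- m
  }
  out
}

#' Extract first matching endpoint events from a registry
#'
#' Filters diagnosis events whose 3-character ICD category falls in the
#' endpoint's inclusive ranges and returns each participant's earliest
#' matching date. Unparseable codes are skipped and counted in the
#' `"rejects"` attribute.
#'
#' @param registry Registry tibble: `participant_id`, `event_date`,
#'   `event_type`, `icd_version`, `icd_code`.
#' @param definition An [endpoint_definition()].
#' @return Tibble `participant_id`, `first_event_date`; attribute
#'   `"rejects"` holds the skipped unparseable rows.
#' @export
extract_endpoint_events <- function(registry, definition) {
  diag <- dplyr::filter(registry, .data$event_type == "diagnosis")
  if (nrow(diag) == 0) {
    out <- tibble(participant_id = character(), first_event_date = as.Date(character()))
    attr(out, "rejects") <- diag
    return(out)
  }
  m <- icd_matches(diag$icd_version, diag$icd_code, definition)
  rejects <- diag[is.na(m), ]
  if (nrow(rejects)) {
    warn(paste0(nrow(rejects), " registry codes did not parse and were skipped"))
  }
  out <- diag[!is.na(m) & m, ] |>
    group_by(.data$participant_id) |>
    summarise(first_event_date = min_date(.data$event_date), .groups = "drop")
  attr(out, "rejects") <- rejects
  out
}

#' Build follow-up records for one endpoint
#'
#' Entry is the exam-2 blood-sampling date; exit is the earliest of the
#' endpoint event, death, emigration, and the endpoint's registry censor
#' date; the event indicator is true only when the exit is the endpoint
#' event itself (for all-cause mortality, death is the event). Participants
#' diagnosed with the endpoint before entry (prevalent cases) are excluded,
#' and deaths act as censoring in the disease analyses.
#'
#' @param cohort Tibble with `participant_id`, `entry_date`, and any
#'   covariates to carry (e.g. the exam-2 record with quartile labels).
#' @param registry Registry event tibble (see [simulate_registry()]).
#' @param definition An [endpoint_definition()].
#' @return Tibble of follow-up records: entry/exit dates, `time_years`,
#'   `event` (logical), covariates; attribute `"n_prevalent"` counts the
#'   excluded prevalent cases.
#' @export
build_followup <- function(cohort, registry, definition) {
  if (!all(c("participant_id", "entry_date") %in% names(cohort))) {
    abort("cohort needs participant_id and entry_date")
  }
  entry <- as.Date(cohort$entry_date)
  if (anyNA(entry)) abort("entry dates must be complete")

  deaths <- registry |>
    dplyr::filter(.data$event_type == "death") |>
    group_by(.data$participant_id) |>
    summarise(death_date = min_date(.data$event_date), .groups = "drop")
  emig <- registry |>
    dplyr::filter(.data$event_type == "emigration") |>
    group_by(.data$participant_id) |>
    summarise(emigration_date = min_date(.data$event_date), .groups = "drop")

  is_mortality <- definition$name == "all_cause_mortality"
  fu <- cohort |>
    mutate(entry_date = entry) |>
    left_join(deaths, by = "participant_id") |>
    left_join(emig, by = "participant_id")

  if (!is_mortality) {
    ev <- extract_endpoint_events(registry, definition)
    fu <- left_join(fu, ev, by = "participant_id")
    prevalent <- !is.na(fu$first_event_date) & fu$first_event_date < fu$entry_date
    n_prev <- sum(prevalent)
    fu <- fu[!prevalent, ]
  } else {
    fu$first_event_date <- fu$death_date
    n_prev <- 0L
  }

  cand <- cbind(
    event = as.numeric(fu$first_event_date),
    death = if (is_mortality) NA_real_ else as.numeric(fu$death_date),
    emigration = as.numeric(fu$emigration_date),
    censor = as.numeric(definition$censor_date)
  )
  exit_num <- apply(cand, 1, min, na.rm = TRUE)
  fu$exit_date <- as.Date(exit_num, origin = "1970-01-01")
  fu$event <- !is.na(fu$first_event_date) &
    as.numeric(fu$first_event_date) == exit_num
  if (any(fu$exit_date < fu$entry_date)) {
    abort("internal error: follow-up exit precedes entry")
  }
  fu$time_years <- pmax(0.5, as.numeric(fu$exit_date - fu$entry_date)) / 365.25
  fu <- select(fu, -"death_date", -"emigration_date")
  attr(fu, "n_prevalent") <- n_prev
  attr(fu, "endpoint") <- definition$name
  fu
}
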