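#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every knob of the synthetic study: cohort size,
#' the cross-sectional age structure of telomere length, the true attrition
#' process, the measurement-noise model, age-confounded lifestyle variables
#' with (by default) zero effect on true attrition, the exam-2 batch offset,
#' and the mortality/morbidity hazards used by [simulate_registry()].
#'
#' Defaults encode the study conditions the pipeline is validated against:
#' a cross-sectional slope of -20 bp per year of age explaining roughly 8%
#' of telomere-length variance, mean true attrition -19.3 bp/year, a median
#' inter-examination gap near 9.3 years (SD 0.43), and lifestyle variables
#' whose distributions drift with age but which do not touch true attrition.
#'
#' @param n_participants Cohort size (default 4576).
#' @param seed Integer RNG seed; every generator call is deterministic given
#'   the seed.
#' @param age_range Ages at exam 1 are uniform on this interval (years).
#' @param tl_intercept_bp,tl_age_slope_bp_per_year Cross-sectional true
#'   telomere length mean structure: `intercept + slope * age` (bp).
#' @param between_person_sd_bp SD of the stable person-level deviation (bp).
#' @param measurement_sd_bp SD of the independent per-exam measurement error
#'   (bp scale).
#' @param mean_attrition_bp_per_year,attrition_sd_bp_per_year Distribution of
#'   true per-year attrition (negative = loss).
#' @param lifestyle_effect_on_attrition Additive effect of the standardized
#'   lifestyle burden score on true attrition (bp/year per SD); 0 is the
#'   confounded-null condition.
#' @param exam_gap_mean_years,exam_gap_sd_years Inter-examination gap.
#' @param exam2_batch_offset_bp Systematic bp offset added to every exam-2
#'   measurement (different DNA storage/isolation batch); the age
#'   recalibration step is expected to remove it.
#' @param mortality_baseline_hazard Hazard per year at the reference age
#'   (70 y) and reference telomere length.
#' @param mortality_age_log_hr Log hazard ratio per year of age at exam 2.
#' @param mortality_tl_log_hr_per_kbp Log hazard ratio per kilobase of
#'   *shorter* true telomere length at exam 2.
#' @param morbidity_rates Named per-year incidence rates for the disease
#'   endpoints (`cancer`, `copd`, `dm2`, `icvd`, `ihd`).
#' @param emigration_fraction Fraction of participants who emigrate during
#'   follow-up (default 39/4576).
#' @param tl_floor_bp Truncation floor for true telomere length (bp).
#' @return A validated list of class `telo_generator_config`.
#' @export
generator_config <- function(n_participants = 4576,
                             seed = 1L,
                             age_range = c(40, 80),
                             tl_intercept_bp = 5600,
                             tl_age_slope_bp_per_year = -20,
                             between_person_sd_bp = 700,
                             measurement_sd_bp = 500,
                             mean_attrition_bp_per_year = -19.3,
                             attrition_sd_bp_per_year = 5,
                             lifestyle_effect_on_attrition = 0,
                             exam_gap_mean_years = 9.3,
                             exam_gap_sd_years = 0.43,
                             exam2_batch_offset_bp = 300,
                             mortality_baseline_hazard = 0.013,
                             mortality_age_log_hr = 0.09,
                             mortality_tl_log_hr_per_kbp = 0.15,
                             morbidity_rates = c(
                               cancer = 0.005, copd = 0.0025, dm2 = 0.0025,
                               icvd = 0.0025, ihd = 0.005
                             ),
                             emigration_fraction = 39 / 4576,
                             tl_floor_bp = 200) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    age_range = age_range, tl_intercept_bp = tl_intercept_bp,
    tl_age_slope_bp_per_year = tl_age_slope_bp_per_year,
    between_person_sd_bp = between_person_sd_bp,
    measurement_sd_bp = measurement_sd_bp,
    mean_attrition_bp_per_year = mean_attrition_bp_per_year,
    attrition_sd_bp_per_year = attrition_sd_bp_per_year,
    lifestyle_effect_on_attrition = lifestyle_effect_on_attrition,
    exam_gap_mean_years = exam_gap_mean_years,
    exam_gap_sd_years = exam_gap_sd_years,
    exam2_batch_offset_bp = exam2_batch_offset_bp,
    mortality_baseline_hazard = mortality_baseline_hazard,
    mortality_age_log_hr = mortality_age_log_hr,
    mortality_tl_log_hr_per_kbp = mortality_tl_log_hr_per_kbp,
    morbidity_rates = morbidity_rates,
    emigration_fraction = emigration_fraction,
    tl_floor_bp = tl_floor_bp
  )
  stopifnot(
    cfg$n_participants > 0,
    length(cfg$age_range) == 2, diff(cfg$age_range) > 0,
    cfg$between_person_sd_bp >= 0, cfg$measurement_sd_bp >= 0,
    cfg$attrition_sd_bp_per_year >= 0,
    cfg$exam_gap_mean_years > 0, cfg$exam_gap_sd_years >= 0,
    cfg$emigration_fraction >= 0, cfg$emigration_fraction < 1,
    cfg$tl_floor_bp > 0
  )
  structure(cfg, class = "telo_generator_config")
}

#' Generate a synthetic two-examination cohort
#'
#' Draws ages uniformly on the configured range, builds true telomere length
#' as `intercept + slope * age + person effect`, draws true attrition
#' independent of baseline (mean -19.3 bp/y by default), and measures each
#' exam with independent Gaussian error on the bp scale; exam-2 measurements
#' additionally carry the configured batch offset. Lifestyle covariates
#' (current smoking, daily tobacco, weight, height, alcohol, weekly
#' exercise) are drawn with age-dependent means or prevalences, so they are
#' confounded with age — and hence with cross-sectional telomere length —
#' while having, by default, no effect on true attrition.
#'
#' @param config A [generator_config()].
#' @return List with tibbles `exam1`, `exam2` (one exam record per
#'   participant: dates, age, covariates, measured `tl_bp`) and `truth`
#'   (latent state for parameter-recovery tests).
#' @examples
#' cohort <- generate_cohort(generator_config(n_participants = 200, seed = 7))
#' nrow(cohort$exam1)
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "telo_generator_config")) {
    config <- do.call(generator_config, config)
  }
  set.seed(config$seed)
  n <- config$n_participants
  id <- sprintf("P%05d", seq_len(n))

  age1 <- runif(n, config$age_range[1], config$age_range[2])
  gap <- pmax(0.5, rnorm(n, config$exam_gap_mean_years, config$exam_gap_sd_years))
  age2 <- age1 + gap

  sex <- if_else(runif(n) < 0.55, "female", "male")
  male <- sex == "male"

  # lifestyle: age-confounded distributions, standardized burden score
  p_smoke <- stats::plogis(-0.35 - 0.008 * (age1 - 60))
  smoking1 <- runif(n) < p_smoke
  tobacco1 <- if_else(smoking1, rgamma(n, shape = 4, scale = 4), 0)
  height <- rnorm(n, if_else(male, 1.77, 1.64), 0.065)
  bmi1 <- rnorm(n, 24.5 + 0.055 * (age1 - 60), 3.8)
  weight1 <- bmi1 * height^2
  alcohol1 <- pmax(0, rnorm(n, if_else(male, 160, 80) + 0.4 * (age1 - 60), 90))
  exercise1 <- rlnorm(n, meanlog = log(5.5) - 0.016 * (age1 - 60), sdlog = 0.6)

  burden <- scale(cbind(
    smoking1, bmi1, -exercise1
  ))
  burden_score <- as.numeric(rowMeans(burden))

  person_effect <- rnorm(n, 0, config$between_person_sd_bp)
  true_tl1 <- pmax(
    config$tl_floor_bp,
    config$tl_intercept_bp + config$tl_age_slope_bp_per_year * age1 + person_effect
  )
  attrition <- rnorm(
    n, config$mean_attrition_bp_per_year, config$attrition_sd_bp_per_year
  ) + config$lifestyle_effect_on_attrition * burden_score
  true_tl2 <- pmax(config$tl_floor_bp, true_tl1 + attrition * gap)

  tl1 <- pmax(config$tl_floor_bp, true_tl1 + rnorm(n, 0, config$measurement_sd_bp))
  tl2 <- pmax(
    config$tl_floor_bp,
    true_tl2 + rnorm(n, 0, config$measurement_sd_bp) + config$exam2_batch_offset_bp
  )

  date1 <- as.Date("1991-06-01") + round(runif(n, 0, 3 * 365.25))
  date2 <- date1 + round(gap * 365.25)

  # exam-2 lifestyle drifts mildly from exam 1
  smoking2 <- if_else(smoking1, runif(n) > 0.25, runif(n) < 0.05)
  tobacco2 <- if_else(smoking2, pmax(0, tobacco1 * 0.9 + rnorm(n, 0, 3)), 0)
  weight2 <- weight1 + rnorm(n, 1.5, 4)
  alcohol2 <- pmax(0, alcohol1 + rnorm(n, -5, 40))
  exercise2 <- pmax(0.1, exercise1 * exp(rnorm(n, -0.08, 0.25)))

  exam_tbl <- function(exam_id, date, age, smoking, tobacco, weight,
                       alcohol, exercise, tl) {
    tibble(
      participant_id = id, exam_id = exam_id, exam_date = date,
      age = age, sex = sex,
      current_smoking = smoking, tobacco_g_day = tobacco,
      weight_kg = weight, height_m = height,
      bmi = weight / height^2,
      alcohol_g_week = alcohol, exercise_h_week = exercise,
      tl_bp = tl
    )
  }

  list(
    exam1 = exam_tbl("exam1", date1, age1, smoking1, tobacco1, weight1,
      alcohol1, exercise1, tl1),
    exam2 = exam_tbl("exam2", date2, age2, smoking2, tobacco2, weight2,
      alcohol2, exercise2, tl2),
    truth = tibble(
      participant_id = id,
      true_tl_exam1_bp = true_tl1,
      true_tl_exam2_bp = true_tl2,
      true_attrition_bp_per_year = attrition,
      burden_score = burden_score,
      gap_years = gap
    )
  )
}
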