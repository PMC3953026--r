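#' Heavy alcohol intake classification
#'
#' Heavy intake is a weekly consumption strictly above 87.5 g for women and
#' 175 g for men (one unit of alcohol = 12 g).
#'
#' @param sex `"female"` / `"male"` (vectorised).
#' @param g_per_week Weekly alcohol intake in grams (>= 0).
#' @return Logical vector.
#' @export
classify_heavy_alcohol <- function(sex, g_per_week) {
  if (any(!sex %in% c("female", "male"))) abort("sex must be female or male")
  if (any(g_per_week < 0, na.rm = TRUE)) abort("alcohol intake cannot be negative")
  threshold <- if_else(sex == "female", 87.5, 175)
  g_per_week > threshold
}

#' Convert alcohol grams to standard units
#'
#' One unit of alcohol equals 12 g.
#' @param grams Alcohol mass in grams.
#' @return Units (g / 12).
#' @export
alcohol_units <- function(grams) grams / 12

#' Physical inactivity classification
#'
#' Inactive means less than 4 hours of weekly exercise.
#'
#' @param exercise_h_week Weekly exercise in hours (>= 0).
#' @return Logical vector.
#' @export
classify_physical_inactivity <- function(exercise_h_week) {
  if (any(exercise_h_week < 0, na.rm = TRUE)) abort("exercise hours cannot be negative")
  exercise_h_week < 4
}

#' Impute missing covariates from age and sex
#'
#' Missing *continuous* covariates are replaced by the prediction of a
#' least-squares fit of that covariate on age and sex among complete cases;
#' missing *categorical* covariates get an explicit `"missing"` level
#' rather than being dropped. Imputed cells are flagged in companion
#' `.imputed` columns.
#'
#' @param cohort Tibble with complete `age` and `sex` columns.
#' @param continuous Character vector of continuous covariate columns to
#'   impute (defaults to the numeric lifestyle covariates present).
#' @param categorical Character vector of categorical columns (defaults to
#'   `current_smoking` if present).
#' @return The cohort with imputations applied and `<col>.imputed` flags.
#' @export
impute_covariates <- function(cohort,
                              continuous = intersect(
                                c(
                                  "tobacco_g_day", "weight_kg", "height_m",
                                  "bmi", "alcohol_g_week", "exercise_h_week"
                                ),
                                names(cohort)
                              ),
                              categorical = intersect("current_smoking", names(cohort))) {
  if (!all(c("age", "sex") %in% names(cohort))) abort("cohort needs age and sex")
  if (anyNA(cohort$age) || anyNA(cohort$sex)) abort("age and sex must be complete")
  out <- cohort
  for (col in continuous) {
    miss <- is.na(out[[col]])
    out[[paste0(col, ".imputed")]] <- miss
    if (!any(miss)) next
    cc <- !miss
    if (!any(cc)) abort(paste0("covariate '", col, "' has no complete cases"))
    fit <- lm(
      stats::reformulate(c("age", "sex"), response = col),
      data = out[cc, , drop = FALSE]
    )
    out[[col]][miss] <- predict(fit, newdata = out[miss, , drop = FALSE])
  }
  for (col in categorical) {
    miss <- is.na(out[[col]])
    out[[paste0(col, ".imputed")]] <- miss
    v <- as.character(out[[col]])
    v[miss] <- "missing"
    out[[col]] <- factor(v)
  }
  out
}
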