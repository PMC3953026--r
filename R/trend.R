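#' Trend test of a covariate across telomere-length quartiles
#'
#' Continuous covariates are tested by the least-squares slope on the
#' quartile index (1-4) with its two-sided p-value; binary covariates by
#' the Cochran-Armitage score test for a linear trend in proportions
#' (two-sided).
#'
#' @param covariate Numeric or logical vector aligned with
#'   `quartile_labels`. Missing values are dropped pairwise.
#' @param quartile_labels Integer labels 1-4 from [quartilize()].
#' @return One-row tibble: `method`, `estimate` (slope per quartile step,
#'   or trend in proportions), `p_value`, `n`.
#' @export
trend_test_quartiles <- function(covariate, quartile_labels) {
  keep <- !is.na(covariate) & !is.na(quartile_labels)
  covariate <- covariate[keep]
  q <- as.integer(quartile_labels[keep])
  if (length(unique(q)) < 2) abort("need at least two populated quartiles")

  is_binary <- is.logical(covariate) ||
    all(covariate %in% c(0, 1))

  if (is_binary) {
    x <- tapply(as.numeric(covariate), q, sum)
    n <- tapply(covariate, q, length)
    lev <- as.numeric(names(x))
    if (sum(x) == 0 || sum(x) == sum(n)) {
      return(tibble(
        method = "cochran_armitage", estimate = 0, p_value = 1,
        n = length(covariate)
      ))
    }
    tst <- prop.trend.test(x, n, score = lev)
    slope <- unname(coef(lm(as.numeric(covariate) ~ q))[2])
    tibble(
      method = "cochran_armitage", estimate = slope,
      p_value = unname(tst$p.value), n = length(covariate)
    )
  } else {
    if (sd(covariate) == 0) {
      return(tibble(
        method = "ols_quartile_index", estimate = 0, p_value = 1,
        n = length(covariate)
      ))
    }
    fit <- lm(covariate ~ q)
    sm <- summary(fit)$coefficients
    tibble(
      method = "ols_quartile_index",
      estimate = unname(sm["q", "Estimate"]),
      p_value = unname(sm["q", "Pr(>|t|)"]),
      n = length(covariate)
    )
  }
}

#' Cross-sectional quartile characteristics and trend tests
#'
#' Reproduces the structure of a baseline-characteristics table: for each
#' covariate, per-quartile summaries (mean, or percentage for binaries) and
#' the trend test across quartiles.
#'
#' @param exam Exam table with `tl_bp` plus covariates.
#' @param covariates Named list mapping display names to column names, or a
#'   character vector of columns; defaults to the standard set if present.
#' @return Tibble: one row per covariate with per-quartile summaries,
#'   `estimate`, `p_trend`.
#' @export
quartile_characteristics <- function(exam, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(
      c(
        "age", "current_smoking", "tobacco_g_day", "bmi",
        "heavy_alcohol", "physical_inactivity", "alcohol_g_week",
        "exercise_h_week"
      ),
      names(exam)
    )
  }
  exam <- exam |>
    mutate(
      heavy_alcohol = if ("alcohol_g_week" %in% names(exam)) {
        classify_heavy_alcohol(.data$sex, .data$alcohol_g_week)
      } else {
        NA
      },
      physical_inactivity = if ("exercise_h_week" %in% names(exam)) {
        classify_physical_inactivity(.data$exercise_h_week)
      } else {
        NA
      }
    )
  covariates <- union(covariates, c("heavy_alcohol", "physical_inactivity"))
  q <- quartilize(exam$tl_bp)

  purrr::map_dfr(covariates, function(col) {
    v <- exam[[col]]
    if (is.factor(v)) v <- v == levels(v)[length(levels(v))]
    per_q <- tapply(as.numeric(v), q, mean, na.rm = TRUE)
    tt <- trend_test_quartiles(v, q)
    tibble(
      covariate = col,
      q1 = per_q[["1"]], q2 = per_q[["2"]], q3 = per_q[["3"]], q4 = per_q[["4"]],
      estimate = tt$estimate, p_trend = tt$p_value, n = tt$n
    )
  })
}
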