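#' Assemble the change-predictor design table
#'
#' Builds the standard predictor set for regressions of 10-year
#' telomere-length change: baseline telomere length (bp), age at baseline,
#' baseline and inter-examination daily tobacco, baseline weight and
#' percent weight change, baseline and inter-examination alcohol (12-g
#' units per day), and baseline and inter-examination weekly physical
#' activity. "Between examinations" exposures are the mean of the two
#' exam reports.
#'
#' @param exam1,exam2 Exam tables.
#' @param change Change table from [build_change_table()].
#' @return Tibble: `participant_id`, `change_bp_10y`, `change_pct_10y`,
#'   and the ten predictor columns.
#' @export
change_predictor_table <- function(exam1, exam2, change) {
  e1 <- exam1 |>
    select("participant_id",
      age_baseline = "age",
      tobacco_baseline = "tobacco_g_day", weight_baseline = "weight_kg",
      alcohol1 = "alcohol_g_week", activity_baseline = "exercise_h_week"
    )
  e2 <- exam2 |>
    select("participant_id",
      tobacco2 = "tobacco_g_day", weight2 = "weight_kg",
      alcohol2 = "alcohol_g_week", activity2 = "exercise_h_week"
    )
  change |>
    select("participant_id", baseline_tl_bp = "tl1_bp",
      "change_bp_10y", "change_pct_10y") |>
    left_join(e1, by = "participant_id") |>
    left_join(e2, by = "participant_id") |>
    mutate(
      tobacco_between = (.data$tobacco_baseline + .data$tobacco2) / 2,
      weight_change_pct = 100 * (.data$weight2 - .data$weight_baseline) /
        .data$weight_baseline,
      alcohol_baseline_units_day = alcohol_units(.data$alcohol1) / 7,
      alcohol_between_units_day = alcohol_units((.data$alcohol1 + .data$alcohol2) / 2) / 7,
      activity_between = (.data$activity_baseline + .data$activity2) / 2
    ) |>
    select(
      "participant_id", "change_bp_10y", "change_pct_10y",
      "baseline_tl_bp", "age_baseline",
      "tobacco_baseline", "tobacco_between",
      "weight_baseline", "weight_change_pct",
      "alcohol_baseline_units_day", "alcohol_between_units_day",
      "activity_baseline", "activity_between"
    )
}

lifestyle_predictors <- c(
  "tobacco_baseline", "tobacco_between", "weight_baseline",
  "weight_change_pct", "alcohol_baseline_units_day",
  "alcohol_between_units_day", "activity_baseline", "activity_between"
)

#' Regressions of telomere-length change on its candidate predictors
#'
#' Fits either one linear model per predictor (`"univariable"`) or a joint
#' model with all predictors (`"multivariable"`), reporting coefficients,
#' two-sided 95% confidence intervals and p-values. When
#' `baseline_tl_bp` is among the predictors a derived `baseline_ts_ratio`
#' row is appended with the bp-scale coefficient multiplied by
#' `anchor_bp` (T/S and bp scales differ by exactly the calibrator anchor).
#'
#' @param data Design table from [change_predictor_table()] (or any tibble
#'   with the outcome and predictor columns).
#' @param outcome Outcome column (default `"change_bp_10y"`).
#' @param mode `"univariable"` or `"multivariable"`.
#' @param predictors Predictor columns; defaults to every column except the
#'   outcome(s) and `participant_id`.
#' @param anchor_bp Calibrator anchor used to derive the T/S-scale row.
#' @return Object of class `telo_predictors`; [tidy()] gives the
#'   coefficient table (`term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`, `mode`).
#' @export
fit_change_predictors <- function(data,
                                  outcome = "change_bp_10y",
                                  mode = c("univariable", "multivariable"),
                                  predictors = NULL,
                                  anchor_bp = 5290) {
  mode <- match.arg(mode)
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(data),
      c(outcome, "participant_id", "change_bp_10y", "change_pct_10y")
    )
  }
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }

  coef_rows <- function(fit, terms, n) {
    sm <- summary(fit)$coefficients
    if (any(is.na(coef(fit)[terms]))) {
      bad <- terms[is.na(coef(fit)[terms])]
      abort(paste0("degenerate (collinear) design: ", paste(bad, collapse = ", ")))
    }
    ci <- suppressMessages(confint(fit, level = 0.95))
    tibble(
      term = terms,
      estimate = unname(coef(fit)[terms]),
      conf.low = ci[terms, 1],
      conf.high = ci[terms, 2],
      p.value = sm[terms, "Pr(>|t|)"],
      n = n
    )
  }

  tab <- if (mode == "univariable") {
    purrr::map_dfr(predictors, function(p) {
      d <- data[!is.na(data[[outcome]]) & !is.na(data[[p]]), c(outcome, p)]
      fit <- lm(stats::reformulate(p, response = outcome), data = d)
      coef_rows(fit, p, nrow(d))
    })
  } else {
    d <- data[, c(outcome, predictors)]
    d <- d[complete.cases(d), ]
    fit <- lm(stats::reformulate(predictors, response = outcome), data = d)
    coef_rows(fit, predictors, nrow(d))
  }

  if ("baseline_tl_bp" %in% tab$term) {
    bp <- tab[tab$term == "baseline_tl_bp", ]
    ts <- bp |>
      mutate(
        term = "baseline_ts_ratio",
        estimate = .data$estimate * anchor_bp,
        conf.low = .data$conf.low * anchor_bp,
        conf.high = .data$conf.high * anchor_bp
      )
    tab <- dplyr::bind_rows(tab, ts)
  }
  tab$mode <- mode

  structure(
    list(table = tab, mode = mode, outcome = outcome, anchor_bp = anchor_bp),
    class = "telo_predictors"
  )
}

#' @export
print.telo_predictors <- function(x, ...) {
  cat("<telo_predictors> ", x$mode, " regression of ", x$outcome, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @rdname fit_change_predictors
#' @param x A `telo_predictors` object.
#' @param ... Unused.
#' @method tidy telo_predictors
#' @export
tidy.telo_predictors <- function(x, ...) x$table

#' @rdname fit_change_predictors
#' @method glance telo_predictors
#' @export
glance.telo_predictors <- function(x, ...) {
  tibble(
    mode = x$mode, outcome = x$outcome,
    n_terms = nrow(x$table), anchor_bp = x$anchor_bp
  )
}
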