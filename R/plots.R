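#' Telomere length against age with the fitted cross-sectional trend
#'
#' @param exam Exam table with `age` and `tl_bp`.
#' @return A ggplot.
#' @export
plot_age_trend <- function(exam) {
  ggplot2::ggplot(exam, ggplot2::aes(x = .data$age, y = .data$tl_bp)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "grey30") +
    ggplot2::labs(
      x = "Age (years)", y = "Telomere length (bp)",
      title = "Cross-sectional telomere length by age"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of 10-year telomere-length change
#'
#' @param change Change table from [build_change_table()].
#' @return A ggplot.
#' @export
plot_change_histogram <- function(change) {
  ggplot2::ggplot(change, ggplot2::aes(x = .data$change_bp_10y)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "10-year change (bp)", y = "Participants",
      title = "Distribution of 10-year telomere-length change"
    ) +
    ggplot2::theme_minimal()
}

#' 10-year change against baseline telomere length
#'
#' Visualises regression toward the mean: the strong negative slope of
#' change on measured baseline expected when within-person variability is
#' appreciable.
#'
#' @param change Change table from [build_change_table()].
#' @return A ggplot.
#' @export
plot_change_vs_baseline <- function(change) {
  ggplot2::ggplot(change, ggplot2::aes(x = .data$tl1_bp, y = .data$change_bp_10y)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "grey30") +
    ggplot2::labs(
      x = "Baseline telomere length (bp)", y = "10-year change (bp)",
      title = "Change against baseline (regression toward the mean)"
    ) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot methods
#' @param object Fitted object.
#' @param ... Unused.
#' @rdname telo_autoplot
#' @method autoplot telo_ph
#' @export
autoplot.telo_ph <- function(object, ...) {
  ggplot2::ggplot(
    object$curves,
    ggplot2::aes(x = .data$log_time, y = .data$cloglog, colour = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "ln(analysis time)", y = "-ln(-ln(survival))",
      title = "Proportional-hazards diagnostic",
      subtitle = paste("max pairwise vertical-range statistic:",
        signif(object$distance_stat, 3))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname telo_autoplot
#' @method autoplot telo_cox
#' @export
autoplot.telo_cox <- function(object, ...) {
  d <- dplyr::filter(object$table, .data$quartile > 1)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$quartile), y = .data$hr)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.15
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Quartile (1 = reference)", y = "Hazard ratio (95% CI)",
      title = "Hazard ratios by quartile"
    ) +
    ggplot2::theme_minimal()
}
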