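#' Proportional-hazards model across quartiles of telomere-length change
#'
#' Fits a Cox model with quartile 1 (largest gain / longest telomeres) as
#' the reference category, Efron handling of tied event times, and an
#' optional multivariable adjustment set. The trend p-value comes from a
#' separate model entering the quartile index 1-4 as a single ordinal
#' covariate (two-sided Wald test).
#'
#' @param followup Follow-up table from [build_followup()] with columns
#'   `time_years`, `event`, and `quartile` (labels 1-4).
#' @param adjust Character vector of covariate columns for multivariable
#'   adjustment (default none).
#' @return Object of class `telo_cox`; [tidy()] returns the hazard-ratio
#'   table (quartile, n, events, `hr`, `conf.low`, `conf.high`) and
#'   [glance()] the trend statistics. A `separation` flag is set when the
#'   partial likelihood is monotone (infinite coefficients).
#' @export
fit_cox_quartiles <- function(followup, adjust = NULL) {
  needed <- c("time_years", "event", "quartile")
  if (!all(needed %in% names(followup))) {
    abort(paste("followup needs columns:", paste(needed, collapse = ", ")))
  }
  if (sum(followup$event) == 0) abort("no events; model not estimable")

  followup <- mutate(followup,
    quartile = factor(as.integer(.data$quartile), levels = 1:4)
  )
  rhs <- c("quartile", adjust)
  form <- stats::as.formula(
    paste("survival::Surv(time_years, event) ~", paste(rhs, collapse = " + "))
  )
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = followup, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )

  trend_form <- stats::as.formula(
    paste(
      "survival::Surv(time_years, event) ~ as.numeric(quartile)",
      if (length(adjust)) paste("+", paste(adjust, collapse = " + ")) else ""
    )
  )
  trend_fit <- survival::coxph(trend_form, data = followup, ties = "efron")
  trend_sm <- summary(trend_fit)$coefficients
  trend_loghr <- unname(trend_sm["as.numeric(quartile)", "coef"])
  trend_p <- unname(trend_sm["as.numeric(quartile)", "Pr(>|z|)"])

  sm <- summary(fit)
  counts <- followup |>
    group_by(.data$quartile) |>
    summarise(n = dplyr::n(), events = sum(.data$event), .groups = "drop")
  qterms <- paste0("quartile", 2:4)
  hr_tab <- tibble(
    quartile = 1:4,
    hr = c(1, unname(exp(coef(fit)[qterms]))),
    conf.low = c(NA, sm$conf.int[qterms, "lower .95"]),
    conf.high = c(NA, sm$conf.int[qterms, "upper .95"]),
    p.value = c(NA, sm$coefficients[qterms, "Pr(>|z|)"])
  ) |>
    left_join(counts |> mutate(quartile = as.integer(as.character(.data$quartile))),
      by = "quartile"
    ) |>
    select("quartile", "n", "events", "hr", "conf.low", "conf.high", "p.value")

  structure(
    list(
      table = hr_tab, trend_p = trend_p, trend_loghr = trend_loghr,
      fit = fit, trend_fit = trend_fit, adjust = adjust,
      separation = separation
    ),
    class = "telo_cox"
  )
}

#' @export
print.telo_cox <- function(x, ...) {
  cat("<telo_cox> quartile hazard ratios",
    if (length(x$adjust)) paste0(" (adjusted: ", paste(x$adjust, collapse = ", "), ")"),
    "\n",
    sep = ""
  )
  print(x$table)
  cat(sprintf(
    "trend: log-HR %.3f per quartile step, p = %.3g\n",
    x$trend_loghr, x$trend_p
  ))
  invisible(x)
}

#' @rdname fit_cox_quartiles
#' @param x A `telo_cox` object.
#' @param ... Unused.
#' @method tidy telo_cox
#' @export
tidy.telo_cox <- function(x, ...) x$table

#' @rdname fit_cox_quartiles
#' @method glance telo_cox
#' @export
glance.telo_cox <- function(x, ...) {
  tibble(
    trend_loghr = x$trend_loghr,
    trend_p = x$trend_p,
    n = sum(x$table$n),
    events = sum(x$table$events),
    separation = x$separation
  )
}

#' Log-minus-log proportional-hazards diagnostic
#'
#' Computes, per group, the Kaplan-Meier curve transformed to
#' `-ln(-ln(S(t)))` against `ln(t)`. Under proportional hazards the group
#' curves are vertical translations of each other, so the reported
#' statistic — the largest over group pairs of the range (max minus min)
#' of the vertical distance along a shared log-time grid — is near zero
#' for parallel curves and grows when hazards cross.
#'
#' @param followup Follow-up table with `time_years` and `event`.
#' @param groups Grouping vector aligned with `followup` rows.
#' @return Object of class `telo_ph`: `curves` (tibble `group`,
#'   `log_time`, `cloglog`) and `distance_stat`.
#' @export
ph_diagnostic <- function(followup, groups) {
  groups <- as.character(groups)
  sf <- survival::survfit(
    survival::Surv(time_years, event) ~ g,
    data = mutate(followup, g = groups)
  )
  strata_names <- sub("^g=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble(
    group = strata_names,
    time = sf$time,
    surv = sf$surv
  ) |>
    dplyr::filter(.data$surv > 0, .data$surv < 1, .data$time > 0) |>
    mutate(log_time = log(.data$time), cloglog = -log(-log(.data$surv)))

  zero_event <- setdiff(unique(groups), unique(curves$group))
  if (length(zero_event)) {
    warn(paste(
      "groups with no estimable curve:",
      paste(zero_event, collapse = ", ")
    ))
  }

  # compare only the stable part of each curve: the first few events make
  # -ln(-ln(S)) swing wildly, which would swamp the parallelism statistic
  stable <- dplyr::filter(curves, .data$surv >= 0.05, .data$surv <= 0.95)
  gs <- unique(stable$group)
  dist <- 0
  if (length(gs) >= 2) {
    pairs <- utils::combn(gs, 2, simplify = FALSE)
    for (p in pairs) {
      a <- stable[stable$group == p[1], ]
      b <- stable[stable$group == p[2], ]
      lo <- max(min(a$log_time), min(b$log_time))
      hi <- min(max(a$log_time), max(b$log_time))
      if (hi <= lo) next
      grid <- seq(lo, hi, length.out = 100)
      fa <- stats::approx(a$log_time, a$cloglog, xout = grid, method = "constant", rule = 2)$y
      fb <- stats::approx(b$log_time, b$cloglog, xout = grid, method = "constant", rule = 2)$y
      d <- fa - fb
      dist <- max(dist, diff(range(d)))
    }
  }
  structure(
    list(curves = curves, distance_stat = dist),
    class = "telo_ph"
  )
}

#' @export
print.telo_ph <- function(x, ...) {
  cat("<telo_ph> ", length(unique(x$curves$group)),
    " groups; max pairwise vertical-range statistic ",
    signif(x$distance_stat, 4), "\n",
    sep = ""
  )
  invisible(x)
}
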