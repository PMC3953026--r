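test_that("heavy alcohol and inactivity classifiers use the sex-specific strict thresholds", {
  expect_true(classify_heavy_alcohol("female", 88))
  expect_false(classify_heavy_alcohol("male", 88))
  expect_false(classify_heavy_alcohol("female", 87.5))
  expect_false(classify_heavy_alcohol("male", 175))
  expect_true(classify_heavy_alcohol("male", 175.1))
  expect_error(classify_heavy_alcohol("female", -1), "negative")

  expect_true(classify_physical_inactivity(3.9))
  expect_false(classify_physical_inactivity(4.0))
  expect_true(classify_physical_inactivity(0))
  expect_error(classify_physical_inactivity(-2), "negative")

  expect_equal(alcohol_units(24), 2)
})

test_that("continuous covariates are imputed from age and sex, categoricals get a missing level", {
  set.seed(81)
  n <- 200
  d <- tibble::tibble(
    age = runif(n, 40, 80),
    sex = sample(c("female", "male"), n, replace = TRUE),
    weight_kg = 50 + 0.3 * age + 10 * (sex == "male"),
    current_smoking = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
  complete <- impute_covariates(d)
  expect_equal(complete$weight_kg, d$weight_kg)

  d2 <- d
  d2$weight_kg[7] <- NA
  d2$current_smoking[9] <- NA
  imp <- impute_covariates(d2)
  # the generating rule is exactly linear in age and sex, so the imputed
  # value equals the rule's prediction
  expect_equal(
    imp$weight_kg[7],
    50 + 0.3 * d$age[7] + 10 * (d$sex[7] == "male"),
    tolerance = 1e-8
  )
  expect_true(imp$weight_kg.imputed[7])
  expect_equal(as.character(imp$current_smoking[9]), "missing")
  expect_equal(nrow(imp), n)

  d3 <- d
  d3$weight_kg <- NA_real_
  expect_error(impute_covariates(d3), "no complete cases")
})

test_that("quartile trend tests separate monotone signals and keep their nominal size", {
  set.seed(82)
  q <- rep(1:4, each = 500)

  up <- q * 2 + rnorm(2000, 0, 0.5)
  tt <- trend_test_quartiles(up, q)
  expect_lt(tt$p_value, 1e-6)
  expect_gt(tt$estimate, 0)

  const <- rep(3.3, 2000)
  tc <- trend_test_quartiles(const, q)
  expect_equal(tc$estimate, 0)
  expect_equal(tc$p_value, 1)

  bin_up <- runif(2000) < (0.1 + 0.1 * q)
  tb <- trend_test_quartiles(bin_up, q)
  expect_equal(tb$method, "cochran_armitage")
  expect_lt(tb$p_value, 1e-6)

  # size under the null: independent covariate, rejection rate near alpha
  rejections <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    x <- rnorm(400)
    qq <- sample(1:4, 400, replace = TRUE)
    trend_test_quartiles(x, qq)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.11)
})

test_that("change-predictor regressions recover noiseless coefficients and scale to T/S", {
  set.seed(83)
  d <- tibble::tibble(
    baseline_tl_bp = rnorm(50, 5000, 800),
    change_bp_10y = -0.5 * baseline_tl_bp + 2000
  )
  fit <- suppressWarnings( # noiseless fit: summary warns about a perfect fit
    fit_change_predictors(d, predictors = "baseline_tl_bp")
  )
  tab <- tidy(fit)
  bp <- tab[tab$term == "baseline_tl_bp", ]
  expect_equal(bp$estimate, -0.5, tolerance = 1e-10)
  expect_equal(bp$conf.high - bp$conf.low, 0, tolerance = 1e-8)

  ts <- tab[tab$term == "baseline_ts_ratio", ]
  expect_equal(ts$estimate, -0.5 * 5290, tolerance = 1e-8)
  expect_equal(ts$p.value, bp$p.value)

  # a perfectly collinear design is refused with the term named
  d$dup <- d$baseline_tl_bp * 2
  expect_error(
    suppressWarnings(fit_change_predictors(d,
      predictors = c("baseline_tl_bp", "dup"),
      mode = "multivariable"
    )),
    "collinear"
  )
})

test_that("under pure regression toward the mean the baseline coefficient matches r - 1", {
  # r * sd2/sd1 = 0.39 reproduces a baseline-TL slope of about -0.61
  tr <- make_test_retest(5e4, r = 0.39, seed = 84)
  d <- tibble::tibble(
    baseline_tl_bp = tr$baseline,
    change_bp_10y = tr$followup - tr$baseline
  )
  fit <- fit_change_predictors(d, predictors = "baseline_tl_bp")
  est <- tidy(fit)$estimate[1]
  expect_lt(abs(est - (-0.61)), 0.02)
})

test_that("ICD category matching honours versions, ranges and boundaries", {
  expect_true(icd_matches("ICD10", "C50", endpoint_definition("cancer")))
  expect_true(icd_matches("ICD10", "D09", endpoint_definition("cancer")))
  expect_false(icd_matches("ICD10", "D10", endpoint_definition("cancer")))
  expect_true(icd_matches("ICD8", "412", endpoint_definition("ihd")))
  expect_false(icd_matches("ICD10", "J40", endpoint_definition("copd")))
  expect_true(icd_matches("ICD10", "J41", endpoint_definition("copd")))
  expect_true(icd_matches("ICD10", "G45", endpoint_definition("icvd")))
  expect_true(icd_matches("ICD10", "E14", endpoint_definition("dm2")))
  # subcodes inherit their category
  expect_true(icd_matches("ICD10", "C50.9", endpoint_definition("cancer")))
  expect_true(is.na(icd_matches("ICD10", "5xx", endpoint_definition("cancer"))))
})

test_that("endpoint extraction takes the earliest match, idempotently and order-independently", {
  reg <- tibble::tibble(
    participant_id = c("a", "a", "a", "b", "c"),
    event_date = as.Date(c("2003-05-01", "2001-02-03", "2005-01-01", "2004-04-04", "2002-02-02")),
    event_type = c("diagnosis", "diagnosis", "diagnosis", "diagnosis", "death"),
    icd_version = c("ICD10", "ICD10", "ICD10", "ICD8", NA),
    icd_code = c("C50", "C34", "J44", "412", NA)
  )
  ev <- extract_endpoint_events(reg, endpoint_definition("cancer"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$first_event_date, as.Date("2001-02-03"))

  shuffled <- reg[c(5, 3, 1, 4, 2), ]
  ev2 <- extract_endpoint_events(shuffled, endpoint_definition("cancer"))
  expect_equal(dplyr::arrange(ev2, participant_id), dplyr::arrange(ev, participant_id))

  bad <- reg
  bad$icd_code[1] <- "???"
  expect_warning(
    ev3 <- extract_endpoint_events(bad, endpoint_definition("cancer")),
    "did not parse"
  )
  expect_equal(nrow(attr(ev3, "rejects")), 1)
})

test_that("follow-up excludes prevalent cases, censors at deaths, and reconciles counts", {
  cohort <- tibble::tibble(
    participant_id = c("a", "b", "c", "d"),
    entry_date = as.Date("2002-06-01")
  )
  reg <- tibble::tibble(
    participant_id = c("a", "b", "c"),
    event_date = as.Date(c("1995-03-01", "2005-08-09", "2010-01-01")),
    event_type = c("diagnosis", "diagnosis", "death"),
    icd_version = c("ICD10", "ICD10", NA),
    icd_code = c("C50", "C61", NA)
  )
  fu <- build_followup(cohort, reg, endpoint_definition("cancer"))
  # prevalent cancer (participant a) is excluded
  expect_false("a" %in% fu$participant_id)
  expect_equal(attr(fu, "n_prevalent") + nrow(fu), nrow(cohort))
  # incident cancer is an event at its date
  expect_true(fu$event[fu$participant_id == "b"])
  expect_equal(fu$exit_date[fu$participant_id == "b"], as.Date("2005-08-09"))
  # death censors the cancer analysis before the registry end
  crow <- fu[fu$participant_id == "c", ]
  expect_false(crow$event)
  expect_equal(crow$exit_date, as.Date("2009-12-31")) # cancer registry ends first
  # no events at all: administrative censoring
  drow <- fu[fu$participant_id == "d", ]
  expect_false(drow$event)
  expect_equal(drow$exit_date, as.Date("2009-12-31"))
  expect_true(all(fu$exit_date >= as.Date("2002-06-01")))

  # for mortality, the death IS the event
  fum <- build_followup(cohort, reg, endpoint_definition("all_cause_mortality"))
  expect_equal(nrow(fum), 4)
  expect_true(fum$event[fum$participant_id == "c"])
  expect_equal(
    fum$exit_date[fum$participant_id == "a"], as.Date("2011-06-07")
  )
})

test_that("Cox quartile models fix the reference at 1.00 and find the trend", {
  fu <- make_quartile_followup(8000, loghr_per_step = 0.25, seed = 91)
  fit <- fit_cox_quartiles(fu)
  tab <- tidy(fit)
  expect_equal(tab$hr[tab$quartile == 1], 1.00)
  expect_true(all(diff(tab$hr) > 0))
  expect_lt(abs(glance(fit)$trend_loghr - 0.25), 0.06)
  expect_lt(glance(fit)$trend_p, 1e-6)
  expect_equal(sum(tab$n), 8000)

  expect_error(
    fit_cox_quartiles(dplyr::mutate(fu, event = FALSE)),
    "no events"
  )
})

test_that("the log-minus-log diagnostic separates proportional from crossing hazards", {
  set.seed(92)
  n <- 4000
  # shared Weibull shape, hazards proportional with HR = 2
  shape <- 1.5
  t1 <- rweibull(n, shape, scale = 10)
  t2 <- rweibull(n, shape, scale = 10 / 2^(1 / shape))
  fu <- tibble::tibble(
    time_years = pmin(c(t1, t2), 12),
    event = c(t1, t2) <= 12
  )
  g <- rep(c("ref", "double"), each = n)
  ph_ok <- ph_diagnostic(fu, g)
  expect_lt(ph_ok$distance_stat, 0.5)

  # identical groups: distance essentially zero
  fu_same <- tibble::tibble(time_years = pmin(t1, 12), event = t1 <= 12)
  ph_same <- ph_diagnostic(
    dplyr::bind_rows(fu_same, fu_same),
    rep(c("g1", "g2"), each = n)
  )
  expect_lt(ph_same$distance_stat, 1e-10)

  # crossing hazards: early-risk vs late-risk groups
  t3 <- rweibull(n, 0.6, scale = 8)
  t4 <- rweibull(n, 3.0, scale = 8)
  fu_x <- tibble::tibble(
    time_years = pmin(c(t3, t4), 12),
    event = c(t3, t4) <= 12
  )
  ph_x <- ph_diagnostic(fu_x, rep(c("early", "late"), each = n))
  expect_gt(ph_x$distance_stat, ph_ok$distance_stat * 2)
})
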