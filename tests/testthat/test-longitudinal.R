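test_that("age recalibration restores exam-1 coefficients and keeps residual variance", {
  co <- generate_cohort(generator_config(n_participants = 3000, seed = 41))
  cal <- age_recalibrate_exam2(co$exam1, co$exam2)

  f1 <- lm(tl_bp ~ age, data = co$exam1)
  f2raw <- lm(tl_bp ~ age, data = co$exam2)
  f2cal <- lm(tl_bp ~ age, data = cal)
  expect_equal(coef(f2cal), coef(f1), tolerance = 1e-10)
  expect_equal(var(resid(f2cal)), var(resid(f2raw)), tolerance = 1e-10)

  # idempotence
  cal2 <- age_recalibrate_exam2(co$exam1, cal)
  expect_equal(cal2$tl_bp, cal$tl_bp, tolerance = 1e-10)

  # identity when exam 2 already sits on the exam-1 line
  e2 <- co$exam1
  cal3 <- age_recalibrate_exam2(co$exam1, e2)
  expect_equal(cal3$tl_bp, e2$tl_bp, tolerance = 1e-10)

  degenerate <- dplyr::mutate(co$exam2, age = 60)
  expect_error(age_recalibrate_exam2(co$exam1, degenerate), "age trend")
})

test_that("an injected exam-2 batch offset is removed by recalibration", {
  cfg_off <- generator_config(n_participants = 4576, seed = 42, exam2_batch_offset_bp = 300)
  cfg_no <- generator_config(n_participants = 4576, seed = 42, exam2_batch_offset_bp = 0)
  off <- generate_cohort(cfg_off)
  no <- generate_cohort(cfg_no)

  # the offset is really there before calibration ...
  expect_equal(mean(off$exam2$tl_bp) - mean(no$exam2$tl_bp), 300, tolerance = 1)

  # ... and calibration returns the offset cohort to the no-offset level
  cal_off <- age_recalibrate_exam2(off$exam1, off$exam2)
  expect_lt(abs(mean(cal_off$tl_bp) - mean(no$exam2$tl_bp)), 100)

  # calibration of the offset and no-offset cohorts coincide exactly:
  # an additive shift moves only the fitted intercept, not the residuals
  cal_no <- age_recalibrate_exam2(no$exam1, no$exam2)
  expect_equal(cal_off$tl_bp, cal_no$tl_bp, tolerance = 1e-9)
})

test_that("10-year change uses exact calendar time over 365.25-day years", {
  expect_equal(
    ten_year_change_bp(4000, as.Date("1991-07-01"), 4000, as.Date("2001-07-01")),
    0
  )
  d <- as.Date("1992-03-04")
  expect_equal(
    ten_year_change_bp(4000, d, 4100, d + 3652.5), 100,
    tolerance = 1e-9
  )
  # frozen from date arithmetic: gap 1991-06-01 .. 2000-11-15 is 3455 days
  gap_days <- as.numeric(as.Date("2000-11-15") - as.Date("1991-06-01"))
  expect_equal(gap_days, 3455)
  expect_equal(
    ten_year_change_bp(5000, "1991-06-01", 4800, "2000-11-15"),
    -200 / (3455 / 365.25) * 10,
    tolerance = 1e-9
  )
  expect_equal(
    round(ten_year_change_bp(5000, "1991-06-01", 4800, "2000-11-15"), 1),
    -211.4
  )
  expect_error(ten_year_change_bp(4000, d, 4000, d), "postdate")
})

test_that("percent change is relative to baseline", {
  expect_equal(ten_year_change_pct(5000, 4800), -4)
  expect_equal(ten_year_change_pct(4000, 4000), 0)
  expect_equal(ten_year_change_pct(2000, 3000), 50)
  expect_error(ten_year_change_pct(0, 3000), "> 0")
})

test_that("quartile labels split evenly, place the largest values first, and absorb ties downward", {
  set.seed(51)
  v <- sample(seq_len(10000), 4576)
  q <- quartilize(v)
  expect_equal(as.vector(table(q)), rep(1144L, 4))
  expect_true(all(v[q == 1] > max(v[q == 2])))

  q8 <- quartilize(c(8, 7, 6, 5, 4, 3, 2, 1))
  expect_equal(as.vector(table(q8)), rep(2L, 4))
  expect_equal(q8[1], 1L)

  # ties at a boundary go to the lower-numbered quartile, so sizes wobble
  vt <- sort(sample(seq_len(9000), 4576), decreasing = TRUE)
  b <- quantile(vt, 0.75, names = FALSE)
  vt[abs(vt - b) < 4] <- round(b)
  qt <- quartilize(vt)
  sizes <- as.vector(table(qt))
  expect_equal(sum(sizes), 4576L)
  expect_true(all(abs(sizes - 1144) <= 7))

  expect_error(quartilize(1:3), "at least 4")
})

test_that("quartile-median RDR reproduces trivial and bivariate-normal cases", {
  set.seed(61)
  x <- rnorm(400)
  same <- regression_dilution_ratio(x, x)
  expect_equal(same$rdr, 1.0)

  tr <- make_test_retest(1e5, r = 0.7, seed = 62)
  # the mean statistic is exactly calibrated to the correlation ...
  rm_ <- regression_dilution_ratio(tr$baseline, tr$followup, statistic = "mean")
  expect_lt(abs(rm_$rdr - 0.7), 0.02)
  # ... while the median statistic carries its documented small upward bias
  rmed <- regression_dilution_ratio(tr$baseline, tr$followup)
  expect_gt(rmed$rdr, 0.7 - 0.02)
  expect_lt(rmed$rdr, 0.7 + 0.09)

  expect_error(regression_dilution_ratio(rep(1, 10), rnorm(10)), "spread")
  expect_error(regression_dilution_ratio(1:4, 1:4), "at least 8")
})

test_that("change summaries count losers, gainers and extremes", {
  expect_equal(change_summary(c(-5, -1, -0.1))$fraction_lost, 1)
  s <- change_summary(c(-10, 10))
  expect_equal(s$fraction_lost, 0.5)
  expect_equal(s$fraction_gained, 0.5)
  expect_equal(s$mean_change_bp_per_year, 0)

  s0 <- change_summary(c(-10, 0, 10))
  expect_equal(s0$fraction_zero, 1 / 3)
  expect_error(change_summary(numeric(0)), "no change")
})

test_that("pure regression toward the mean matches the closed-form slope", {
  # with true change independent of baseline, slope of (followup - baseline)
  # on baseline is r * sd2/sd1 - 1
  for (r in c(0.3, 0.5, 0.7)) {
    tr <- make_test_retest(5e4, r = r, seed = 70 + round(10 * r))
    slope <- coef(lm(I(followup - baseline) ~ baseline, data = tr))[[2]]
    expect_lt(abs(slope - (r - 1)), 0.02)
  }
})

test_that("the change table wires dates, quartiles and calibration together", {
  co <- generate_cohort(generator_config(n_participants = 1200, seed = 71))
  ch <- build_change_table(co$exam1, co$exam2)
  expect_equal(nrow(ch), 1200)
  expect_true(all(sort(unique(ch$change_quartile)) == 1:4))
  expect_true(all(ch$gap_years > 0))
  # quartile 1 of change holds the largest gains
  expect_gt(
    min(ch$change_bp_10y[ch$change_quartile == 1]),
    max(ch$change_bp_10y[ch$change_quartile == 4])
  )
  # percent and bp change agree in sign
  expect_true(all(sign(ch$change_pct_10y) == sign(ch$tl2_bp - ch$tl1_bp)))
})
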