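test_that("plate normalization factors are global/plate ratios", {
  pn <- plate_normalization(
    list(telomere = 13.26, albumin = 15.0),
    list(telomere = 13.00, albumin = 15.0)
  )
  expect_equal(pn$factor_tel, 13.00 / 13.26, tolerance = 1e-12)
  expect_equal(pn$factor_alb, 1.0)

  same <- plate_normalization(
    list(telomere = 13, albumin = 15), list(telomere = 13, albumin = 15)
  )
  expect_equal(same$factor_tel, 1.0)

  expect_error(
    plate_normalization(
      list(telomere = 0, albumin = 15), list(telomere = 13, albumin = 15)
    ),
    "invalid calibrator"
  )
})

test_that("Ct calibration is multiplicative", {
  expect_equal(calibrate_ct(18, 1), 18)
  expect_equal(calibrate_ct(18, 13 / 13.26), 18 * 13 / 13.26, tolerance = 1e-12)
  expect_equal(calibrate_ct(20, 1.05), 21)
  expect_error(calibrate_ct(18, 0), "positive")
})

test_that("delta-delta-Ct quantification honours the calibrator anchor", {
  # sample identical to the calibrator: exactly the anchor
  expect_equal(quantify_sample(13, 15, calibrator_delta_ct = 2)$abs_tl_bp, 5290)
  # one cycle of delta-delta-Ct doubles / halves
  expect_equal(quantify_sample(12, 15, 2)$abs_tl_bp, 10580)
  expect_equal(quantify_sample(14, 15, 2)$abs_tl_bp, 2645)
  expect_error(quantify_sample(13, 15, 2, anchor_bp = -1), "anchor_bp")
})

test_that("telomere length is strictly decreasing in the telomere Ct", {
  tel <- seq(10, 18, by = 0.25)
  tl <- quantify_sample(tel, 15, 2)$abs_tl_bp
  expect_true(all(diff(tl) < 0))
})

test_that("plate-set quantification round-trips synthesized plates", {
  set.seed(21)
  s <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:60),
    tl_bp = runif(60, 2500, 9500)
  )
  w <- synthesize_plate_cts(s, seed = 22, well_sd = 0, plate_capacity = 25)
  q <- quantify_plate_set(w)
  got <- q$results$abs_tl_bp[match(s$sample_id, q$results$sample_id)]
  expect_lt(max(abs(got - s$tl_bp) / s$tl_bp), 1e-9)
  expect_true(all(q$results$qc_status == "ok"))

  # with modest well noise the recovery stays accurate in the median
  wn <- synthesize_plate_cts(s, seed = 23, well_sd = 0.05, plate_capacity = 25)
  qn <- quantify_plate_set(wn)
  gotn <- qn$results$abs_tl_bp[match(s$sample_id, qn$results$sample_id)]
  expect_lt(median(abs(gotn - s$tl_bp) / s$tl_bp), 0.05)
})

test_that("a sample with the calibrator's Cts reads the anchor on every plate, shifted or not", {
  w <- calibrator_twin_plates()
  q <- quantify_plate_set(w)
  twin <- q$results[q$results$sample_id == "twin", ]
  expect_equal(twin$abs_tl_bp, 5290, tolerance = 1e-12)

  # per-plate check: both plates' internal controls agree despite the
  # plate-2 shift being normalized away only approximately for additive
  # shifts -- but the twin (= calibrator) is exact by construction
  expect_equal(nrow(q$calibration), 2)
})

test_that("a multiplicative plate shift cancels exactly within a plate set", {
  set.seed(31)
  s <- tibble::tibble(sample_id = sprintf("a%02d", 1:20), tl_bp = runif(20, 3000, 8000))
  s2 <- dplyr::mutate(s, sample_id = sub("^a", "b", sample_id))
  w1 <- synthesize_plate_cts(s, seed = 32, well_sd = 0, plate_capacity = 20)
  w2 <- synthesize_plate_cts(s2, seed = 32, well_sd = 0, plate_capacity = 20) |>
    dplyr::mutate(plate_id = "plate_shifted", ct = ct * 1.03)
  q <- quantify_plate_set(dplyr::bind_rows(w1, w2))
  a <- q$results$abs_tl_bp[match(s$sample_id, q$results$sample_id)]
  b <- q$results$abs_tl_bp[match(s2$sample_id, q$results$sample_id)]
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("primer-dimer wells are dropped and missing calibrators fail a plate", {
  w <- calibrator_twin_plates()
  # poison one twin telomere well with a wild Ct but flag it as primer dimer
  i <- which(w$sample_id == "twin" & w$assay == "telomere" & w$plate_id == "p1")[1]
  w$ct[i] <- 30
  w$primer_dimer[i] <- TRUE
  q <- quantify_plate_set(w)
  expect_equal(
    q$results$abs_tl_bp[q$results$sample_id == "twin"], 5290,
    tolerance = 1e-12
  )

  # a plate with no calibrator marks its samples failed
  w2 <- dplyr::filter(
    calibrator_twin_plates(),
    !(plate_id == "p2" & role == "calibrator")
  )
  q2 <- quantify_plate_set(w2)
  p2 <- q2$controls[q2$controls$plate_id == "p2", ]
  expect_true(all(p2$qc_status == "failed"))
})

test_that("the latest non-failed measurement wins when samples are rerun", {
  w <- calibrator_twin_plates()
  # on plate 1 the twin has only one valid telomere well -> rerun_needed;
  # plate 2 carries the clean rerun
  drop <- which(w$plate_id == "p1" & w$sample_id == "twin" & w$assay == "telomere")[1:2]
  w <- w[-drop, ]
  q <- quantify_plate_set(w, min_valid = 2)
  twin <- q$results[q$results$sample_id == "twin", ]
  expect_equal(nrow(twin), 1)
  expect_equal(twin$plate_id, "p2")
  expect_equal(twin$qc_status, "ok")
})
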