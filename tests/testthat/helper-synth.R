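# paired bivariate-normal measurements with correlation r and given SDs
make_test_retest <- function(n, r, sd1 = 1, sd2 = 1, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  tibble::tibble(
    baseline = sd1 * z1,
    followup = sd2 * (r * z1 + sqrt(1 - r^2) * z2)
  )
}

# follow-up table with a known per-quartile log hazard ratio
make_quartile_followup <- function(n, loghr_per_step, base_rate = 0.05,
                                   horizon = 10, seed = 1) {
  set.seed(seed)
  q <- sample(1:4, n, replace = TRUE)
  rate <- base_rate * exp(loghr_per_step * (q - 1))
  t <- rexp(n, rate)
  tibble::tibble(
    quartile = q,
    time_years = pmin(t, horizon),
    event = t <= horizon
  )
}

# two-plate well table where one participant carries exactly the
# calibrator's Ct values; plate 2 runs systematically 0.4 cycles high
calibrator_twin_plates <- function(ct_tel = 13.1, ct_alb = 15.2) {
  plate <- function(id, shift) {
    one <- tibble::tibble(
      plate_id = id,
      sample_id = c("K562", "NTERA2", "twin"),
      role = c("calibrator", "internal_control", "participant"),
      tel = c(ct_tel, ct_tel + 1, ct_tel) + shift,
      alb = c(ct_alb, ct_alb + 1, ct_alb) + shift
    )
    one <- one[rep(1:3, each = 3), ] # triplicate wells
    dplyr::bind_rows(
      dplyr::transmute(one, plate_id, sample_id, role,
        assay = "telomere", ct = tel, primer_dimer = FALSE
      ),
      dplyr::transmute(one, plate_id, sample_id, role,
        assay = "albumin", ct = alb, primer_dimer = FALSE
      )
    )
  }
  dplyr::bind_rows(plate("p1", 0), plate("p2", 0.4))
}
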