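---
title: "Methods: telomere length quantification and longitudinal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telomere length quantification and longitudinal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotrack)
```

# The measurement model

Monochrome multiplex qPCR amplifies the telomere repeat and a single-copy
reference gene (albumin) in the same well, read at different temperatures.
A cycle-threshold (Ct) value is one unit per doubling of template, so the
gap `Ct_alb − Ct_tel` measures the log2 abundance of telomere repeat
relative to the single-copy gene. `telotrack`'s quantification chain is:

1. **Replicate QC** (`qc_replicates()`). Participants run in
   quadruplicate, controls in triplicate. Outlying wells are removed and
   the mean Ct recomputed. Two policies are provided:
   * `literal_2sd`: drop a well if it lies outside the replicate group's
     own mean ± 2 SD (sample SD, n−1 denominator). For a quadruplicate
     this rule is *provably vacuous*: with the sample SD the largest
     attainable |z| is (n−1)/√n = 1.5 < 2, so it can never exclude a
     well. The test suite confirms this by brute force over 10⁵ random
     quadruplicates.
   * `leave_one_out_2sd` (default): judge each well against the mean ±
     2 SD of the *other* replicates. This catches a single aberrant well
     with certainty when the others are tight, which is what an outlier
     rule is for. The vacuity of the literal rule is why the leave-one-out
     variant is the default; the literal rule is retained as an option.
   Samples with fewer than `min_valid` (default 2) surviving wells per
   assay are flagged `rerun_needed`; a sample may appear on further plates
   and the latest non-failed measurement wins.

2. **Plate normalization** (`plate_normalization()`). Every plate carries
   a K562 calibrator. Per assay, `factor_plate = Ct_cal(all plates) /
   Ct_cal(this plate)`, and `Ct_calibrated = Ct × factor_plate`. The
   normalization is *multiplicative on the Ct scale*, exactly as the
   formula is written, not additive and not multiplicative on 2^−Ct. A
   consequence worth knowing: a multiplicative plate disturbance cancels
   exactly (tested), whereas an additive cycle shift cancels only
   approximately. The plate simulator therefore defaults to
   multiplicative batch effects (`plate_shift = "multiplicative"`), with
   the additive variant available for sensitivity analysis.

3. **ΔΔCt quantification** (`quantify_sample()`).
   `ΔCt_X = Ct_alb − Ct_tel` (calibrated), `ΔΔCt = ΔCt_X − ΔCt_K562`,
   T/S ratio `= 2^ΔΔCt`, and absolute telomere length
   `absTL = 2^ΔΔCt × anchor_bp`. The anchor (default **5,290 bp**) is the
   calibrator's externally determined absolute telomere length; it is a
   configuration value because its derivation (against a Southern-blot
   calibrated reference DNA) is outside this package's scope. Defining
   T/S as 2^ΔΔCt makes the T/S-scale and bp-scale regression coefficients
   consistent by exactly the anchor factor; the alternative reading of
   T/S as a plain ratio of Ct values is not used because it is
   dimensionally incompatible with the 2^ΔΔCt machinery that the absTL
   formula requires. A sample presenting the calibrator's own Ct values
   returns exactly the anchor on every plate — the pipeline's invariant
   anchor point.

4. **Precision** (`assay_cv()`): CV% = 100·SD/mean with the sample SD,
   computed across plates on the internal control (NTERA-2, inter-assay)
   and across each participant's replicate wells (intra-assay).

# Longitudinal machinery

**Age recalibration** (`age_recalibrate_exam2()`). DNA storage and
isolation differences between examinations can shift a whole exam's
measurements, which would masquerade as population-wide telomere change.
The transform fits `TL ~ age` at both exams and replaces each exam-2
value with `a₁ + b₁·age₂ᵢ + r₂ᵢ` (exam-1 coefficients, participant's own
exam-2 residual). This is the minimal transform with both desired
properties, which hold *by construction and exactly*: re-regressing
calibrated TL₂ on age₂ returns (a₁, b₁) to machine precision, and the
exam-2 residual variance is untouched. It removes any additive batch
offset exactly (an offset moves only the fitted intercept) and is
idempotent. The cost is equally structural: the population mean change
after calibration is pinned to the exam-1 age gradient (`b₁ × gap`), so
*average* change over the cohort is no longer an estimate of mean
attrition — only within-person relative change remains interpretable.
With the generator defaults (cross-sectional slope −20 bp/y, mean
attrition −19.3 bp/y) the two nearly coincide, which is why the
attrition-recovery test uses a ±2 bp/y band rather than pure Monte-Carlo
error.

**10-year change** (`ten_year_change_bp()`): exact calendar-day gap
divided by 365.25 days/year, scaled to 10 years; percent change is
relative to baseline. No timezone or leap-second handling — registry and
exam dates are civil dates.

**Quartiles** (`quartilize()`): empirical 25/50/75 % cuts (type-7
quantiles); quartile 1 holds the longest telomeres or largest gains.
Values tied with a boundary go to the lower-numbered quartile, so ties
perturb group sizes instead of being split — 4,576 distinct values give
exactly 1,144 per quartile, tied boundaries give slightly uneven groups
that still partition the cohort.

**Regression dilution ratio** (`regression_dilution_ratio()`): quartilize
the baseline, freeze membership, and compare the extreme-quartile
contrast at follow-up to baseline. The default per-quartile statistic is
the **median**, the form in which such contrasts are printed alongside
interquartile ranges. A caveat the package documents and tests: on
bivariate-normal data the median RDR sits slightly *above* the
test-retest correlation r (≈ +0.03 to +0.06 for r between 0.3 and 0.7),
because within a baseline quartile the follow-up is a skewed truncated
normal plus symmetric noise and the median of that convolution is pulled
toward the subgroup mean. The `statistic = "mean"` variant is exactly
calibrated (conditional quartile means scale by r·σ₂/σ₁) and is the right
choice when the RDR is meant to estimate r itself.

**Regression toward the mean.** When true change is independent of true
baseline, the regression of measured change on measured baseline has
slope `r·σ₂/σ₁ − 1` — strictly negative even with zero true association.
This closed form is exercised directly in the tests (slope within ±0.02
at n = 10⁵ for r ∈ {0.3, 0.5, 0.7}) and explains why baseline level
dominates any change-predictor table: a large negative baseline
coefficient is the *expected* signature of within-person variability, not
evidence of biology.

# Association analyses

* **Trend tests** (`trend_test_quartiles()`): the method behind a
  "P for trend" column is rarely stated, so a choice had to be made:
  least-squares slope on the quartile index (1–4) for continuous
  covariates, Cochran–Armitage score test (`stats::prop.trend.test`) for
  binaries, both two-sided. Rank-based alternatives (e.g. Cuzick) exist;
  the chosen tests are conventional and their null size is verified by
  simulation.
* **Covariate handling**: heavy alcohol intake is strictly above
  87.5 g/week (women) / 175 g/week (men), one unit = 12 g; physical
  inactivity is < 4 h weekly exercise. Missing continuous covariates are
  imputed from a least-squares fit on age and sex among complete cases;
  missing categoricals get an explicit `"missing"` level. "Between
  examinations" exposures are the mean of the two exam reports — an
  assumption, flagged here, since the aggregation is not otherwise
  specified.
* **Endpoints** (`endpoint_definition()`, `build_followup()`): ICD
  matching uses the 3-character category only (subcodes inherit), ranges
  inclusive; registry end dates are 2011-06-07 (death), 2009-12-31
  (cancer), 2011-05-10 (other diseases). Entry is the exam-2
  blood-sampling date; prevalent cases are excluded per endpoint, which
  is why per-endpoint denominators differ slightly. Deaths censor the
  disease analyses (no competing-risk modelling — plain proportional
  hazards is the target design). Same-day exits are floored at half a
  day so event times stay positive.
* **Cox models** (`fit_cox_quartiles()`): quartile 1 is the reference
  (HR ≡ 1.00), Efron approximation for the heavily tied registry dates,
  trend p from the ordinal quartile index as a single covariate,
  two-sided Wald intervals. Monotone-likelihood separation is flagged,
  not silently accepted.
* **Proportional-hazards diagnostic** (`ph_diagnostic()`): per-group
  `−ln(−ln S(t))` vs `ln t`; under proportional hazards the curves are
  vertical translations, so the statistic is the largest over group pairs
  of the range of their vertical distance on a shared log-time grid.
  The comparison is restricted to the stable part of each curve
  (survival between 5 % and 95 %): the first few Kaplan–Meier steps make
  the transform swing wildly and would swamp the parallelism signal.

# What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws ages uniformly on 40–80 y, true telomere length
as `5600 − 20·age + N(0, 700²)` bp truncated at 200 bp (positivity for
the log2 plate synthesis), true attrition `N(−19.3, 5²)` bp/year
independent of baseline, an exam gap `N(9.3, 0.43²)` years, and
independent `N(0, 500²)` bp measurement error per exam; exam 2 carries a
+300 bp batch offset by default so the age recalibration has something
real to correct. These moments give a closed-form cross-sectional
R² = b²·Var(age) / (b²·Var(age) + σ_b² + σ_m²) ≈ 0.067, within the
intended ≈ 0.08 ballpark.

Lifestyle covariates are *confounded with age by construction* —
inactivity prevalence and BMI rise with age, smoking mildly so — while
their effect on true attrition defaults to zero
(`lifestyle_effect_on_attrition = 0`). This encodes the null worth
testing: cross-sectional lifestyle–telomere associations that arise
purely through age confounding, with no longitudinal effect to find. The
registry simulator draws deaths from a Gompertz-type hazard
(log-linear in exam-2 age and in kilobases of shorter true telomere
length; baseline 0.013/y at age 70, log-HR 0.09/y of age and 0.15/kbp,
chosen to give a realistic ~20 % ten-year mortality in a 40–80 y cohort),
disease diagnoses as constant-rate processes started 15 years before
exam 1 (so prevalent-case exclusion is exercised) carrying concrete
ICD-8/ICD-10 codes (ICD-8 before 1994, except cancer which its registry
codes in ICD-10 throughout), and emigration for a small fraction
(39/4,576).

What the generator does **not** emulate: non-Gaussian telomere
distributions, assay drift within a plate, DNA-quality covariates,
age-dependent disease incidence, inter-examination mortality (the cohort
is conditioned on surviving to exam 2, so survivorship/collider effects
on the exam-2 sample are out of scope), competing-risk structure, or any
demographic realism beyond the stated moments. Passing tests therefore
validate the *pipeline's arithmetic and statistical behaviour under the
stated model*, not the biology of any real cohort; cohort-specific
coefficients from real studies are not reproducible from synthetic data
and are not targets.

# Validation problem sizes

The test suite exercises: exact identities at machine precision
(calibrator anchor, zero-noise round trip of 500 samples through plate
synthesis and quantification, recalibration contract at n = 4,576); 10⁵
random quadruplicates for the QC vacuity theorem and 10³ planted outliers
for the leave-one-out policy; closed-form regression-toward-the-mean
checks at n = 10⁵; one n = 20,000 cohort for cross-sectional trend
rejection plus 50 replicate cohorts of n = 5,000 for the null rejection
rates of the lifestyle change-predictors (8 terms × 50 replicates) and
of the Cox change-quartile trend (3 endpoints × 50 replicates); and
n = 20,000 for recovery of an injected 0.2 per-quartile log hazard
ratio within ±0.05. These sizes were chosen so each check's Monte-Carlo
error is small against its tolerance.

# Known limitations

* The literal ±2 SD rule is kept only for fidelity; it cannot exclude
  anything from a quadruplicate, so its selection does no QC.
* The median-based RDR is a biased estimator of the test-retest
  correlation (see above); use `statistic = "mean"` for estimation.
* After age recalibration the cohort-mean change is structural, not
  estimated; report within-person contrasts only.
* Deaths are censoring events in disease analyses; with heavy competing
  mortality the cause-specific hazard ratios reported here do not equal
  subdistribution (Fine–Gray) effects, which are out of scope.
* ICD matching is category-level; analyses needing 4th-character
  granularity require a finer matcher.
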