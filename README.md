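# telotrack

Leukocyte telomere length from raw qPCR plates to prospective epidemiology,
in one tested R pipeline.

Telomeres shorten with age, and short telomeres have been associated
cross-sectionally with smoking, adiposity, and physical inactivity. Whether
those lifestyle factors actually *accelerate telomere attrition* — or are
merely confounded with age — can only be addressed with repeated
measurements, and repeated biomarker measurements bring their own trap:
regression toward the mean, which manufactures spurious "change" that
correlates with baseline. `telotrack` implements the full analysis chain
for this kind of study, for biostatisticians and epidemiologists working
with monochrome multiplex qPCR (MMqPCR) telomere data and registry
follow-up:

* **Quantification** (`quantify_plate_set()`): well-level Ct values →
  replicate QC → plate normalization against a K562 calibrator → the
  ΔΔCt calculation → absolute telomere length. For sample *X*:

  ```
  ΔCt_X  = Ct_alb(X, calibrated) − Ct_tel(X, calibrated)
  ΔΔCt   = ΔCt_X − ΔCt_K562
  absTL  = 2^ΔΔCt × 5,290 bp
  ```

  with `Ct_calibrated = Ct × factor_plate` and
  `factor_plate = Ct_K562(all plates) / Ct_K562(this plate)` per assay.
  Inter- and intra-assay CVs (`100·SD/mean`) are reported alongside.

* **Longitudinal change** (`build_change_table()`): inter-examination age
  recalibration (restores the exam-1 TL-on-age regression exactly while
  keeping exam-2 residual variance, removing storage/isolation batch
  shifts), exact-time 10-year change
  `(TL₂ − TL₁) / (days/365.25) × 10`, percent change, examination-specific
  quartiles, and the quartile-median regression dilution ratio
  (`regression_dilution_ratio()`).

* **Association analyses** (`quartile_characteristics()`,
  `fit_change_predictors()`, `fit_cox_quartiles()`): cross-sectional
  quartile trend tests (OLS on quartile index; Cochran–Armitage for
  binaries), uni-/multivariable regressions of change on its candidate
  predictors with age/sex imputation of missing covariates, ICD-8/ICD-10
  registry endpoint extraction with per-endpoint censor dates, follow-up
  construction with prevalent-case exclusion, and proportional-hazards
  quartile models (Efron ties) with ordinal trend tests and
  `-ln(-ln S)` diagnostics.

* **Synthetic cohort** (`generate_cohort()`, `synthesize_plate_cts()`,
  `simulate_registry()`): a generator that emulates the statistical
  structure such a study assumes — a −20 bp/year cross-sectional age
  gradient explaining ≈ 8 % of variance, mean true attrition −19.3
  bp/year, age-confounded lifestyle with zero effect on true attrition,
  and a mortality hazard rising with age and with shorter telomeres — so
  every downstream stage runs and can be validated without access to any
  individual-level study data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` and `plot_*()` for figures.

## Worked example

```r
library(telotrack)

cfg     <- generator_config(n_participants = 4576, seed = 7)
cohort  <- generate_cohort(cfg)
change  <- build_change_table(cohort$exam1, cohort$exam2)  # age-recalibrated
change_summary(change)
#>       n fraction_lost fraction_gained fraction_zero mean_change_bp_per_year
#> 1  4576         0.600           0.400             0                   -19.6
```

60 % of participants lost and 40 % gained telomere length, with a mean
annualized change of −19.6 bp/year — the generator's attrition level as
seen through the age-recalibrated measurements. The cross section shows
the familiar age gradient (`lm(tl_bp ~ age)` gives a slope of −19.6
bp/year, R² = 0.065: age explains only a few percent of telomere-length
variance even when the trend is unambiguous).

Prospective follow-up of change quartiles against the simulated registry:

```r
registry <- simulate_registry(cohort$truth, cohort$exam2, cfg, exam1 = cohort$exam1)
base <- dplyr::inner_join(
  dplyr::transmute(cohort$exam2, participant_id, entry_date = exam_date, age, sex),
  dplyr::select(change, participant_id, quartile = change_quartile),
  by = "participant_id")
fu <- build_followup(base, registry, endpoint_definition("all_cause_mortality"))
fit_cox_quartiles(fu, adjust = c("age", "sex"))
#> <telo_cox> quartile hazard ratios (adjusted: age, sex)
#>   quartile     n events    hr conf.low conf.high p.value
#> 1        1  1144    266 1       NA         NA    NA
#> 2        2  1144    239 0.844    0.709      1.01  0.0576
#> 3        3  1144    266 0.949    0.800      1.12  0.545
#> 4        4  1144    265 0.995    0.839      1.18  0.956
#> trend: log-HR 0.010 per quartile step, p = 0.716
```

Change quartiles do not predict mortality (trend p = 0.72) — exactly what
the generator encodes: the hazard depends on age and on telomere *level*,
while measured change is dominated by within-person variability. The
contrast between strong cross-sectional lifestyle trends and null
longitudinal/prospective associations is the pipeline's headline pattern;
`run_pipeline()` produces the full report bundle (characteristics tables,
change-predictor regressions, per-endpoint hazard ratios) in one call.

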