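# untwistr

Functional-data analysis of left-ventricular (LV) strain and rotation
curves in maintenance hemodialysis cohorts.

Hemodialysis removes fluid faster than the vasculature refills, and the
resulting intravascular hypovolemia stresses LV filling. The hypothesis
this package operationalizes is that *diastolic untwist* — the decay of
LV torsion after its systolic peak, which generates the suction that
keeps the ventricle filling under hypovolemia — shapes both intradialytic
systolic blood pressure (SBP) and survival in patients with preserved or
mildly reduced ejection fraction. Rather than reducing each
speckle-tracking curve to a single peak value, the whole curve enters the
model as a functional covariate.

`untwistr` is for biostatisticians and cardiology/nephrology researchers
who export strain and rotation traces from speckle-tracking software and
want a tested, reproducible pipeline for:

* **Curve preparation** — time-normalizing traces of arbitrary length to
  a fixed 33-sample cardiac-cycle grid (`resample_trace()`), building
  torsion as apical-minus-basal rotation (`compute_torsion()`), and
  extracting peak features (`summarize_curve()`).
* **Scalar-on-function regression (SoFR)** — the repeated-SBP model

  ```
  SBP_isj = alpha + occ_j + z_i' gamma + SUM_m INT beta_m(t) X_im(t) dt + b_i + e_isj
  ```

  with patient random intercepts `b_i ~ N(0, sigma_b^2)` for the 3
  sessions x 7 occasions of SBP per patient, and the binomial-logit
  mortality model `logit P(death_i) = alpha + SUM_m INT beta_m(t) X_im(t) dt`.
  Coefficient functions `beta(t)` are penalized B-splines; smoothing
  parameters and variance components are selected by REML in an
  augmented-ridge formulation written for this package (and cross-checked
  against `mgcv` and `lme4` in the test suite).
* **Inference** — pointwise Wald bands (`pointwise_band()`),
  patient-level (cluster) bootstrap bands (`bootstrap_band()`), and
  global Wald tests of `beta(t) = 0` (`global_pvalue()`).
* **Interpretable effects** — odds ratios or mmHg changes for curve
  perturbations such as "GLS 5 points more negative after t = 0.5 of the
  cycle" (`perturbation()`, `perturbation_effect()`).
* **A calibrated synthetic-cohort generator**
  (`synthetic_config()`, `generate_cohort()`, `recovery_experiment()`)
  that emulates the cohort's curve shapes, covariate moments, SBP model
  and 8% mortality, so every stage is testable without patient data.

## Worked example

```r
library(untwistr)

cohort  <- generate_cohort(synthetic_config(), seed = 2024)
fit_sbp <- fit_sofr_gaussian(cohort)
fit_sbp
#> <sofr_fit> family gaussian, 1470 obs / 70 patients
#>   sigma_b 7.87, sigma_eps 9.89, variance explained 58.5%
#>   AIC 10983.5, total edf 72.2
#>   scalar covariates:
#>              term estimate   ci_low  ci_high        p
#>               age -0.29861 -0.43198 -0.16523 1.14e-05
#>               sex -0.69310 -5.13992  3.75371 7.60e-01
#>      hypertension  0.87032 -4.03348  5.77412 7.28e-01
#>          diabetes  6.17711  1.02331 11.33091 1.88e-02
#>  dialysis_vintage -0.44900 -0.77384 -0.12417 6.74e-03
#>     ultrafiltrate -0.00158 -0.00458  0.00142 3.02e-01
#>      ivc_diameter  1.28044  0.56108  1.99981 4.85e-04
#>   lv_mass_indexed  0.11975  0.05513  0.18437 2.81e-04
#>   beta_torsion(t): edf 2.08, lambda 84.4
#>   beta_gls(t): edf 2.02, lambda 126
#>   beta_rv_free_wall(t): edf 2.40, lambda 11.9
```

The cohort was simulated with true age, ultrafiltrate and IVC effects of
-0.30 mmHg/year, -0.001 mmHg/mL and +1.33 mmHg/mm; the fit recovers each
within its Wald CI. `sigma_b`/`sigma_eps` are the patient and residual
SDs in mmHg, and "variance explained" is `1 - RSS/TSS` on the
fixed-plus-random fitted values.

```r
global_pvalue(fit_sbp, "torsion")   # 0.491 for this replicate
fit_mort <- fit_sofr_binomial(cohort)
perturbation_effect(fit_mort, perturbation("gls", -5))
#> <perturbation_effect> gls -5 units over t in [0.500, 1.000]:
#>   odds ratio 3.410 (95% CI 0.121-95.981)
```

The perturbation effect answers: how do the odds of death change for a
patient whose GLS curve is 5 percentage points more negative than the
mean curve throughout diastole? (At 70 patients and 6 or so events a
single replicate's CI is rightly enormous.)

`run_pipeline(pipeline_config(...))` chains simulate/load -> fit ->
effects -> report into an output directory with a checksummed manifest;
`render_report()` writes coefficient tables, `beta(t)` band plots and
mean-curve plots as CSV + image pairs.

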