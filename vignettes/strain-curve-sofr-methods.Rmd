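---
title: "Scalar-on-function regression for LV strain curves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalar-on-function regression for LV strain curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(untwistr)
```

This vignette documents the statistical machinery in `untwistr`: the
models it fits, the numerical choices behind them, what the
synthetic-cohort generator does and does not emulate, and the package's
known limitations.

## 1. Curves and their preparation

Speckle-tracking software exports one numeric series per modality and
cardiac cycle: global longitudinal strain (GLS, %), apical and basal
rotation (degrees), and right-ventricular free-wall strain (%). Series
lengths differ with heart rate and frame rate, so curves are
time-normalized to a common grid before any comparison:

* **Grid.** `t_l = (l-1)/32`, `l = 1..33`, i.e. 33 samples spanning the
  closed interval `[0, 1]` of cardiac-cycle proportion. Endpoints are
  included so the exported first and last samples are preserved exactly.
  `t = 0` is simply the start of the exported trace; no cardiac-phase
  (end-diastole vs. QRS) interpretation is attached, because exports do
  not carry that information.
* **Interpolation.** Input samples are placed at equally spaced
  positions spanning `[0, 1]` and linearly interpolated
  (`stats::approx`). Linear interpolation is shape-preserving — the
  output can never overshoot the input range — and is exactly consistent
  with the trapezoid quadrature used later, so no further approximation
  error enters the design matrix.
* **Torsion** is the pointwise difference apical minus basal rotation.
  Its decline after the systolic peak is the diastolic untwist.
* **Peaks.** For shortening modalities (GLS, RV free wall) the peak is
  the most negative sample; for rotations/torsion the maximum. Ties take
  the earliest time, which makes the summary deterministic and
  order-independent.

## 2. The regression models

### 2.1 Repeated SBP (Gaussian, multilevel)

For patient $i$, session $s = 1..3$, occasion $j = 1..7$:

$$SBP_{isj} = \alpha + occ_j + z_i^\top\gamma +
  \sum_m \int_0^1 \beta_m(t)\,X_{im}(t)\,dt + b_i + \varepsilon_{isj},$$

with $b_i \sim N(0, \sigma_b^2)$, $\varepsilon_{isj} \sim N(0,
\sigma_\varepsilon^2)$. The scalar covariates $z_i$ are age, sex,
hypertension, diabetes, dialysis vintage, ultrafiltrate volume, IVC
diameter and indexed LV mass; the functional covariates $X_{im}$ are the
torsion, GLS and RV free-wall curves.

Design choices that were genuinely open:

* **Occasion effects.** SBP declines systematically over a dialysis
  session. The seven measurement occasions enter as fixed indicator
  effects (reference: occasion 1); this is assumption-light about the
  shape of the decline and can be toggled off
  (`sofr_options(occasion_effects = FALSE)`).
* **Random structure.** A single patient-level random intercept; no
  session-level effect. Sessions are expected to be exchangeable within
  patient once the occasion trend is removed.
* **Missing data.** Missing SBP entries are dropped row-wise; curves and
  scalar covariates must be complete. No imputation is attempted.

### 2.2 Mortality (binomial, patient level)

$$\mathrm{logit}\,P(death_i = 1) = \alpha +
  \int \beta_{gls}(t) X_{i,gls}(t)\,dt +
  \int \beta_{tor}(t) X_{i,tor}(t)\,dt.$$

With few events, the primary model carries no scalar covariates; an
age-adjusted variant (`adjust_age = TRUE`) is provided as a sensitivity
analysis. Coefficient functions are on the log-odds scale.

## 3. Penalized estimation

### 3.1 Basis and penalty

Each $\beta(t)$ is a penalized B-spline: `K = 9` cubic basis functions
with a second-order difference penalty on the coefficients
(`basis_spec()`). Nine cubic splines on 33 grid points leave ample
flexibility; the penalty controls the effective degrees of freedom, so
`K` mostly needs to be "large enough" and results are insensitive to it
in the usual P-spline way. Knots follow the Eilers–Marx convention:
uniformly spaced with `0` and `1` among the knots and the sequence
extended past the boundary. This convention was chosen deliberately over
clamped (repeated) boundary knots because it makes the difference
penalty's null space *exactly* the polynomials in `t` — as the smoothing
parameter grows, $\beta(t)$ converges to a straight line, a property the
test suite checks literally. Partition of unity on `[0, 1]` is preserved.

### 3.2 Quadrature and centering

Integrals are trapezoid sums on the 33-point grid
(`quadrature_weights()`): weights `1/64` at the endpoints, `1/32`
inside. Trapezoid quadrature is exact for the piecewise-linear curve
representation that time-normalization produces, so the functional
design block

$$J_{ik} = \sum_l w_l\,(X_i(t_l) - \bar X(t_l))\,b_k(t_l)$$

carries no additional approximation error. Curves are centered at the
sample mean curve $\bar X$, which decorrelates the intercept from the
functional terms; the centering curve is stored in the fit for use at
prediction time and doubles as the "mean curve" in reports.

### 3.3 REML in an augmented-ridge form

Both fits are solved in one augmented formulation: the design holds the
unpenalized columns plus one penalized block per functional term
(difference penalty $\lambda_m P$) and, for the Gaussian model, the
patient indicator block with ridge penalty $\lambda_b I$ — the random
intercept, with $\lambda_b = \sigma_\varepsilon^2/\sigma_b^2$. At fixed
penalties the estimate is the closed-form generalized ridge
$(C^\top C + S)^{-1} C^\top y$, and the test suite asserts exact
agreement with that closed form.

Smoothing parameters and variance components are selected jointly by
maximizing the exact Gaussian REML criterion (Laplace-approximate for
the binomial working model), profiled over $\sigma_\varepsilon^2$. The
search runs over log-penalties rescaled so each penalty matches its
design block's Frobenius norm — this keeps the optimum near the origin
regardless of covariate units (ultrafiltrate is in mL, age in years) —
with Nelder–Mead inside a soft box of ±18 scaled log-units, restarts on
simplex degeneracy, and golden-section search when only one parameter is
free. On models without functional terms the fit reproduces `lme4::lmer`
REML estimates to ~1e-6, and with functional terms it matches
`mgcv::gam(..., method = "REML")` with `bs = "ps"` terms; both
comparisons are tests, not dependencies.

The binomial model is fitted by penalized IRLS with warm starts across
the REML search and a cold-started final fit (so results do not depend
on the search path). Fitted log-odds beyond ±30 raise a
complete-separation error rather than returning divergent coefficients.

Setting a term's `fixed_lambda` to `Inf` removes its columns entirely,
which constrains $\beta(t) \equiv 0$ exactly — useful for intercept-only
references and null comparisons.

### 3.4 Uncertainty

The coefficient covariance is the Bayesian posterior covariance of the
penalized fit, $V = \hat\sigma^2 (C^\top C + S)^{-1}$ (scale 1 for the
binomial). Pointwise bands propagate $V$ through the basis:
$\hat\beta(t_l) \pm z\,SE(t_l)$. Scalar coefficients get large-sample
Wald CIs with the z quantile.

The **global test** of $\beta_{term} \equiv 0$ is a Wald statistic
computed on the fitted-value scale: with `R` the triangular QR factor of
the term's design block, the statistic uses $R\hat\theta$ and
$R V_{term} R^\top$, truncating the covariance eigendecomposition at the
rounded effective degrees of freedom of the term. Working on $R\theta$
weights coefficient directions by how strongly the observed curves
identify them; testing raw basis coefficients instead wastes the
truncation rank on directions the design barely expresses and can miss
even overwhelming effects. For the Gaussian model the statistic is
referred to an $F(k,\ n_{patients} - k - 1)$ distribution: curves vary
between patients, so the patient count — not the observation count — is
the effective replication, and at 70 patients the chi-square reference
is visibly anti-conservative (simulated type-I error just above 9% at
nominal 5%, versus ~8% with the F reference; the residual inflation
reflects plug-in variance components). The binomial model uses the
upper chi-square tail.

The **cluster bootstrap** resamples patients with replacement — each
resampled patient keeps all sessions and curves, respecting
within-patient correlation — refits per replicate, and forms pointwise
percentile bands. It is deterministic given a seed and errors out if
more than 20% of replicates fail to fit.

### 3.5 Perturbation effects

Reported effects translate $\hat\beta(t)$ into the change in linear
predictor for a constant shift of $\delta$ curve-units over a window,
default $[0.5, 1]$ — the diastolic half of the cycle:
$\eta = \delta \int_{t_0}^{t_1} \hat\beta(t)\,dt$. "5 units" is read in
absolute curve units (percentage points for strain, degrees for
torsion), relative to any reference curve — a constant shift's effect
does not depend on the reference. Window endpoints snap to the nearest
grid points so the trapezoid integral stays exact; the CI is
delta-method Wald on the log-OR (binomial) or mmHg (Gaussian) scale.
Log-effects are exactly linear in $\delta$ and additive over abutting
windows.

## 4. The synthetic-cohort generator

The generator (`synthetic_config()` defaults) emulates the statistical
structure the analysis assumes, calibrated to the cohort's published
summary statistics:

| quantity | default | unit |
|---|---|---|
| patients | 70 | — |
| torsion peak | 25.5 (SD 8.4) | degrees |
| torsion time-to-peak | 0.453 (SD 0.05) | cycle proportion |
| GLS peak | −20.0 (SD 3.83) | % |
| GLS time-to-peak | 0.463 (SD 0.05) | cycle proportion |
| age | 50.4 (SD 14.9) | years |
| female | 41.4% | — |
| hypertension / diabetes | 65.7% / 10% | — |
| ultrafiltrate | 2350 (SD 663) | mL |
| IVC diameter | 16.3 (SD 3.15) | mm |
| indexed LV mass | 111 (SD 39) | g/m² |
| dialysis vintage | gamma, mean 7.84 (SD 5.90) | years |
| true scalar SBP effects | fitted point estimates (e.g. age −0.30, UF −0.001, IVC +1.33) | mmHg per unit |
| σ_b / σ_ε | 8 / 10 | mmHg |
| SBP intercept / occasion slope | 121.5 / −2 | mmHg |
| mortality rate | 8% | — |

Notes on the less obvious rows:

* **Curve template.** Each curve is
  `amplitude × template(t; τ) + smooth noise`, the template a
  beta-density-shaped pulse renormalized to unit peak (zero at both
  cycle ends, skew controlled by a concentration parameter, default 8).
  Amplitude and peak time τ are drawn per patient; τ is truncated to
  (0.1, 0.9) and amplitudes are sign-clamped at 0.5 units so torsion
  stays positive and strain negative. Only peak amplitude/timing
  statistics are calibrated — the template family is *not* traced from
  any figure.
* **Curve noise** is a low-rank Gaussian process (squared-exponential
  kernel, length-scale 0.2 cycle; pointwise SD 0.6° torsion, 0.4%
  strain) so simulated curves stay smooth and physiological.
* **RV free-wall strain** has no published summary in the source
  cohort; the defaults (−26%, SD 5) are typical clinical values and the
  term carries no true effect by default.
* **True functional effects** default to a smooth bump over diastole
  (`sin²(π(t−0.5)/0.5)` for `t > 0.5`) with amplitude +1 mmHg/degree on
  torsion for SBP, and −0.04 (torsion) / −0.10 (GLS) log-odds per unit
  for mortality — qualitative mimics of the reported directions
  (protective untwist, adverse negative diastolic GLS), documented as
  illustrative shapes, not estimates.
* **σ_b, σ_ε and the occasion slope** are not published; 8 and 10 mmHg
  give realistic within-patient correlation (~0.4) and a 12 mmHg decline
  over a session, and both are config fields.
* **SBP intercept** 121.5 mmHg puts the mean pre-dialysis SBP near
  140 mmHg given the covariate means.
* **Mortality intercept** is calibrated per cohort by root finding so
  the cohort-average event probability hits the target rate exactly;
  realized deaths are then a binomial draw.

What the generator does *not* emulate: intradialytic hypotension
events, covariate correlations (covariates are drawn independently),
curve-covariate dependence (e.g. LV mass does not shape the torsion
curve), session-to-session curve variation, or measurement drift.
Passing tests therefore demonstrate that the estimation machinery
recovers truth under the assumed model at the study's scale — not that
the model is correct for any particular real cohort.

## 5. Validation design and problem sizes

The test suite (and `scripts/acceptance.R`) validates at these sizes,
chosen to balance Monte-Carlo error against desk-scale runtimes:

* curve calibration at n = 2000 curves; covariate and mortality
  calibration at n = 5000 patients;
* parameter recovery over 20 replicate cohorts of 70 patients
  (3 × 7 SBP series), requiring mean estimated ultrafiltrate, age and
  IVC coefficients within half a mean SE of truth — at 20 replicates the
  Monte-Carlo error of those means is roughly 0.2–0.5 mean SE, so this
  is a genuine bias check, not a formality;
* type-I error and band coverage over 500 null cohorts of 70 patients
  (rejection rate required in [0.02, 0.09]; mean pointwise coverage of
  the zero function in [0.92, 0.98]);
* oracle equalities (generalized ridge at 1e−8, logistic MLE at 1e−6)
  on single cohorts;
* larger coverage runs (200 replicates) confirm ~95% scalar-CI coverage
  but are not part of the default suite for runtime reasons.

## 6. Known limitations

* Wald bands and tests use plug-in variance components; the residual
  type-I inflation (~8% at nominal 5% with 70 patients) is documented
  above. The cluster bootstrap is the heavier alternative the package
  offers.
* Percentile bootstrap bands inherit the shrinkage of penalized refits
  and can undercover near-null effects in small cohorts.
* The binomial model is patient-level and unpenalized in its intercept
  only; with very few events (≲5) even penalized fits can separate, and
  the package raises an error rather than reporting divergent odds.
* Curves are assumed to cover exactly one cardiac cycle; no cycle
  detection, drift compensation or phase alignment is attempted.
* Time-varying survival modelling is out of scope; mortality is a
  binary endpoint over the follow-up window.
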