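# Shared fixture builders: everything is generated in code.

# A small cohort for fast fitting tests. Binary covariate rates are
# pulled toward 1/2 so tiny cohorts do not draw constant columns.
small_cohort <- function(n = 12, seed = 42, ...) {
  generate_cohort(synthetic_config(
    n_patients = n,
    covariates = list(
      age_mean = 50.4, age_sd = 14.9,
      sex_p = 0.5, hypertension_p = 0.5, diabetes_p = 0.4,
      ultrafiltrate_mean = 2350, ultrafiltrate_sd = 663,
      ivc_mean = 16.3, ivc_sd = 3.15, lvmi_mean = 111, lvmi_sd = 39,
      vintage_mean = 7.84, vintage_sd = 5.90), ...), seed)
}

# Config with every true effect switched off (null model), used by
# type-I-error and coverage simulations.
null_config <- function(n = 70, sigma_b = 8, sigma_eps = 10,
                        occasion_slope = -2) {
  synthetic_config(
    n_patients = n,
    sbp = list(intercept = 140, occasion_slope = occasion_slope,
               gamma = c(age = 0, sex = 0, hypertension = 0, diabetes = 0,
                         dialysis_vintage = 0, ultrafiltrate = 0,
                         ivc_diameter = 0, lv_mass_indexed = 0),
               beta_torsion = 0, beta_gls = 0, beta_rv = 0,
               sigma_b = sigma_b, sigma_eps = sigma_eps))
}

# Reduced SBP model (torsion only, no scalar covariates): fast to fit.
reduced_options <- function(...) {
  sofr_options(functional_terms = "torsion", scalar_terms = character(0),
               ...)
}

# Independent piecewise-linear interpolation oracle (plain loop).
interp_oracle <- function(values, L = 33L) {
  n <- length(values)
  x_in <- (seq_len(n) - 1) / (n - 1)
  x_out <- (seq_len(L) - 1) / (L - 1)
  out <- numeric(L)
  for (l in seq_len(L)) {
    x <- x_out[l]
    j <- findInterval(x, x_in, rightmost.closed = TRUE)
    j <- min(max(j, 1L), n - 1L)
    frac <- (x - x_in[j]) / (x_in[j + 1] - x_in[j])
    out[l] <- (1 - frac) * values[j] + frac * values[j + 1]
  }
  out
}

# Minimal hand-built binomial fit with a constant coefficient function,
# for closed-form perturbation checks.
constant_beta_fit <- function(c0, family = "binomial") {
  spec <- basis_spec()
  K <- spec$n_basis
  structure(list(
    family = family,
    scalar = data.frame(term = "(Intercept)", group = "intercept",
                        estimate = 0, se = 1, ci_low = -2, ci_high = 2,
                        p = 1),
    functional = list(torsion = list(
      term = "torsion", coefs = rep(c0, K), grid = cycle_grid(33),
      beta = rep(c0, 33), se = rep(0.1, 33), Vb = diag(K) * 1e-4,
      edf = 2, lambda = 1, center = NULL, units = "log-odds")),
    spec = spec), class = "sofr_fit")
}
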