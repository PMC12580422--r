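# Synthetic-cohort generator.
#
# Emulates the statistical structure the analysis assumes: unimodal
# strain/rotation curve families calibrated to the cohort's peak
# amplitude and timing statistics, scalar covariates from the published
# moments, repeated SBP from the Gaussian multilevel model, and
# mortality from the binomial scalar-on-function model with the
# intercept calibrated to a target marginal event rate. Every generator
# is a pure function of (config, seed).

#' Synthetic-cohort configuration
#'
#' All distributional parameters of the generator. Defaults reproduce
#' the study-cohort calibration: curve peak amplitudes and timings,
#' covariate moments, true scalar effects equal to the SBP-model point
#' estimates, a torsion effect on SBP concentrated in diastole, a
#' linearly decreasing within-session SBP trend, and an 8% marginal
#' mortality rate.
#'
#' @param n_patients Cohort size, default 70.
#' @param curves Per-modality shape settings: `amp_mean`/`amp_sd` (peak
#'   amplitude, degrees or percent), `peak_time_mean`/`peak_time_sd`
#'   (cycle proportion, truncated to (0.1, 0.9)) and `noise_sd`
#'   (pointwise SD of the smooth residual curve noise).
#' @param template_concentration Sharpness of the unimodal beta-density
#'   pulse template (larger = narrower peak), default 8.
#' @param noise_length_scale Squared-exponential length-scale of the
#'   smooth curve noise, in cycle proportion; default 0.2.
#' @param covariates Moments for the scalar covariates (normal for
#'   continuous, Bernoulli for binary, gamma for dialysis vintage).
#' @param sbp SBP-model truths: `intercept` (mmHg at occasion 1 with all
#'   covariates 0), `occasion_slope` (mmHg change per occasion),
#'   `gamma` (named true scalar effects), `beta_torsion`/`beta_gls`/
#'   `beta_rv` (amplitude of the true functional effect, a smooth bump
#'   over diastole, outcome units per curve-unit), `sigma_b` (patient
#'   random-intercept SD, mmHg), `sigma_eps` (residual SD, mmHg).
#' @param mortality `target_rate` (marginal death probability; intercept
#'   calibrated to it), and diastolic-bump amplitudes `beta_torsion`,
#'   `beta_gls` on the log-odds scale.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_patients = 70L,
    curves = list(
      torsion = list(amp_mean = 25.5, amp_sd = 8.4,
                     peak_time_mean = 0.453, peak_time_sd = 0.05,
                     noise_sd = 0.6),
      gls = list(amp_mean = -20.0, amp_sd = 3.83,
                 peak_time_mean = 0.463, peak_time_sd = 0.05,
                 noise_sd = 0.4),
      rv_free_wall = list(amp_mean = -26.0, amp_sd = 5.0,
                          peak_time_mean = 0.46, peak_time_sd = 0.05,
                          noise_sd = 0.4)),
    template_concentration = 8,
    noise_length_scale = 0.2,
    covariates = list(
      age_mean = 50.4, age_sd = 14.9,
      sex_p = 0.414, hypertension_p = 0.657, diabetes_p = 0.10,
      ultrafiltrate_mean = 2350, ultrafiltrate_sd = 663,
      ivc_mean = 16.3, ivc_sd = 3.15,
      lvmi_mean = 111, lvmi_sd = 39,
      vintage_mean = 7.84, vintage_sd = 5.90),
    sbp = list(
      intercept = 121.5, occasion_slope = -2,
      gamma = c(age = -0.30, sex = 1.4, hypertension = 5.85,
                diabetes = 0.97, dialysis_vintage = -0.45,
                ultrafiltrate = -0.001, ivc_diameter = 1.33,
                lv_mass_indexed = 0.12),
      beta_torsion = 1.0, beta_gls = 0, beta_rv = 0,
      sigma_b = 8, sigma_eps = 10),
    mortality = list(target_rate = 0.08,
                     beta_torsion = -0.04, beta_gls = -0.10)) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients), curves = curves,
    template_concentration = template_concentration,
    noise_length_scale = noise_length_scale,
    covariates = covariates, sbp = sbp, mortality = mortality),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  bad <- character(0)
  if (cfg$n_patients < 2L) bad <- c(bad, "n_patients (< 2)")
  for (m in names(cfg$curves)) {
    cc <- cfg$curves[[m]]
    if (cc$amp_sd < 0) bad <- c(bad, sprintf("curves$%s$amp_sd (< 0)", m))
    if (cc$peak_time_sd < 0)
      bad <- c(bad, sprintf("curves$%s$peak_time_sd (< 0)", m))
    if (cc$noise_sd < 0)
      bad <- c(bad, sprintf("curves$%s$noise_sd (< 0)", m))
    if (cc$peak_time_mean <= 0 || cc$peak_time_mean >= 1)
      bad <- c(bad, sprintf("curves$%s$peak_time_mean (outside (0,1))", m))
  }
  cv <- cfg$covariates
  for (p in c("sex_p", "hypertension_p", "diabetes_p"))
    if (cv[[p]] < 0 || cv[[p]] > 1) bad <- c(bad, paste0(p, " (not in [0,1])"))
  for (s in c("age_sd", "ultrafiltrate_sd", "ivc_sd", "lvmi_sd",
              "vintage_sd"))
    if (cv[[s]] <= 0) bad <- c(bad, paste0(s, " (<= 0)"))
  if (cfg$sbp$sigma_b < 0) bad <- c(bad, "sbp$sigma_b (< 0)")
  if (cfg$sbp$sigma_eps < 0) bad <- c(bad, "sbp$sigma_eps (< 0)")
  if (cfg$mortality$target_rate <= 0 || cfg$mortality$target_rate >= 1)
    bad <- c(bad, "mortality$target_rate (not in (0,1))")
  if (cfg$template_concentration <= 0)
    bad <- c(bad, "template_concentration (<= 0)")
  if (cfg$noise_length_scale <= 0)
    bad <- c(bad, "noise_length_scale (<= 0)")
  if (length(bad))
    stop("invalid synthetic_config fields: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(cfg)
}

# Unimodal skewed pulse: a beta-density-shaped bump with mode tau,
# renormalized to unit peak, zero at both ends of the cycle.
curve_template <- function(t, tau, s) {
  a <- tau * s
  b <- (1 - tau) * s
  out <- numeric(length(t))
  inner <- t > 0 & t < 1
  out[inner] <- exp(a * (log(t[inner]) - log(tau)) +
                      b * (log1p(-t[inner]) - log1p(-tau)))
  out
}

# Low-rank smooth noise factor: eigendecomposition of a squared-
# exponential kernel on the grid, unit pointwise variance.
noise_factor <- function(L, length_scale) {
  tg <- cycle_grid(L)
  Kmat <- exp(-outer(tg, tg, "-")^2 / (2 * length_scale^2))
  eg <- eigen(Kmat, symmetric = TRUE)
  keep <- eg$values > 1e-8 * eg$values[1]
  eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), sum(keep))
}

# True functional-effect shape: smooth bump over the diastolic half of
# the cycle, zero before t = 0.5, unit peak at t = 0.75.
diastole_bump <- function(t) {
  ifelse(t > 0.5, sin(pi * (t - 0.5) / 0.5)^2, 0)
}

true_beta_curves <- function(cfg, L = 33L) {
  tg <- cycle_grid(L)
  list(torsion = cfg$sbp$beta_torsion * diastole_bump(tg),
       gls = cfg$sbp$beta_gls * diastole_bump(tg),
       rv_free_wall = cfg$sbp$beta_rv * diastole_bump(tg))
}

true_beta_mortality <- function(cfg, L = 33L) {
  tg <- cycle_grid(L)
  list(torsion = cfg$mortality$beta_torsion * diastole_bump(tg),
       gls = cfg$mortality$beta_gls * diastole_bump(tg))
}

# RNG-consuming core: draws n curve triplets. Amplitudes are normal
# (sign-clamped at 0.5 units so curves keep their physiological sign),
# peak times normal truncated to (0.1, 0.9), plus smooth zero-mean
# noise.
generate_curves_rng <- function(cfg, n, L = 33L) {
  tg <- cycle_grid(L)
  E <- noise_factor(L, cfg$noise_length_scale)
  out <- list()
  for (m in names(cfg$curves)) {
    cc <- cfg$curves[[m]]
    amp <- stats::rnorm(n, cc$amp_mean, cc$amp_sd)
    amp <- if (cc$amp_mean >= 0) pmax(amp, 0.5) else pmin(amp, -0.5)
    tau <- pmin(pmax(stats::rnorm(n, cc$peak_time_mean, cc$peak_time_sd),
                     0.1), 0.9)
    noise <- matrix(stats::rnorm(n * ncol(E)), n) %*% t(E) * cc$noise_sd
    M <- t(vapply(seq_len(n), function(i)
      amp[i] * curve_template(tg, tau[i], cfg$template_concentration),
      numeric(L))) + noise
    out[[m]] <- unname(M)
  }
  out
}

#' Generate synthetic strain/rotation/torsion curve triplets
#'
#' Each curve is `amplitude * template(t; peak time) + smooth noise`
#' with a skewed unimodal template that is zero at the cycle start;
#' torsion curves are positive-valued, GLS and RV free-wall strain
#' negative-valued. Deterministic given `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param n Number of curve triplets.
#' @param seed Integer RNG seed.
#' @return Named list of `n x 33` matrices (`torsion`, `gls`,
#'   `rv_free_wall`).
#' @export
generate_curves <- function(config, n, seed) {
  validate_synthetic_config(config)
  with_seed(seed, generate_curves_rng(config, n))
}

generate_cohort_rng <- function(cfg) {
  n <- cfg$n_patients
  cv <- cfg$covariates
  pt <- data.frame(
    subject_id = sprintf("p%04d", seq_len(n)),
    age = stats::rnorm(n, cv$age_mean, cv$age_sd),
    sex = stats::rbinom(n, 1, cv$sex_p),
    hypertension = stats::rbinom(n, 1, cv$hypertension_p),
    diabetes = stats::rbinom(n, 1, cv$diabetes_p),
    dialysis_vintage = stats::rgamma(
      n, shape = (cv$vintage_mean / cv$vintage_sd)^2,
      scale = cv$vintage_sd^2 / cv$vintage_mean),
    ultrafiltrate = stats::rnorm(n, cv$ultrafiltrate_mean,
                                 cv$ultrafiltrate_sd),
    ivc_diameter = stats::rnorm(n, cv$ivc_mean, cv$ivc_sd),
    lv_mass_indexed = stats::rnorm(n, cv$lvmi_mean, cv$lvmi_sd),
    stringsAsFactors = FALSE)

  curves <- generate_curves_rng(cfg, n)
  w <- quadrature_weights(33L)
  bt <- true_beta_curves(cfg)
  func_part <- rowSums(vapply(names(bt), function(m)
    drop(curves[[m]] %*% (w * bt[[m]])), numeric(n)))
  gam <- cfg$sbp$gamma
  scal_part <- drop(as.matrix(pt[, names(gam)]) %*% gam)
  b_i <- stats::rnorm(n, 0, cfg$sbp$sigma_b)
  fixed_i <- cfg$sbp$intercept + scal_part + func_part + b_i

  grid <- expand.grid(session = 1:3, occasion = 1:7,
                      patient = seq_len(n))
  occ_eff <- cfg$sbp$occasion_slope * (grid$occasion - 1)
  sbp_val <- fixed_i[grid$patient] + occ_eff +
    stats::rnorm(nrow(grid), 0, cfg$sbp$sigma_eps)
  sbp_val <- pmin(pmax(sbp_val, 31), 299)   # physiological support
  sbp <- data.frame(subject_id = pt$subject_id[grid$patient],
                    session = grid$session, occasion = grid$occasion,
                    sbp = sbp_val, stringsAsFactors = FALSE)

  btm <- true_beta_mortality(cfg)
  eta_m <- rowSums(vapply(names(btm), function(m)
    drop(curves[[m]] %*% (w * btm[[m]])), numeric(n)))
  target <- cfg$mortality$target_rate
  g <- function(a) mean(stats::plogis(a + eta_m)) - target
  if (g(-40) > 0 || g(40) < 0)
    stop("mortality calibration failure: target rate unreachable",
         call. = FALSE)
  alpha_m <- stats::uniroot(g, c(-40, 40), tol = 1e-10)$root
  pt$death <- stats::rbinom(n, 1, stats::plogis(alpha_m + eta_m))

  out <- cohort_data(pt, curves, sbp)
  attr(out, "truth") <- list(
    gamma = gam, intercept = cfg$sbp$intercept,
    occasion_slope = cfg$sbp$occasion_slope,
    beta = bt, beta_mortality = btm, alpha_mortality = alpha_m,
    sigma_b = cfg$sbp$sigma_b, sigma_eps = cfg$sbp$sigma_eps)
  out
}

#' Generate a full synthetic cohort
#'
#' Draws covariates, curve triplets, the 3 x 7 repeated SBP series from
#' the Gaussian multilevel model, and deaths from the binomial
#' scalar-on-function model whose intercept is calibrated by root
#' finding so that the cohort-average event probability equals the
#' target rate. The generating truths are attached as
#' `attr(, "truth")`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @return A [cohort_data()] object with a `"truth"` attribute.
#' @export
generate_cohort <- function(config, seed) {
  validate_synthetic_config(config)
  with_seed(seed, generate_cohort_rng(config))
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates cohorts, fits the Gaussian multilevel
#' scalar-on-function model, and summarizes recovery of the generating
#' truths: per scalar covariate the mean estimate, empirical bias, mean
#' standard error and 95% CI coverage; per functional term the mean
#' integrated squared error of \eqn{\hat\beta(t)}.
#'
#' @param config A [synthetic_config()].
#' @param n_replicates Number of replicate cohorts (>= 2).
#' @param seed Integer RNG seed.
#' @param spec A [basis_spec()].
#' @param options Fitting options, see [sofr_options()].
#' @return A list of class `recovery_summary` with data frames `scalars`
#'   and `functional`.
#' @export
recovery_experiment <- function(config, n_replicates, seed,
                                spec = basis_spec(),
                                options = sofr_options()) {
  validate_synthetic_config(config)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) stop("need n_replicates >= 2", call. = FALSE)
  gam <- config$sbp$gamma
  terms <- options$functional_terms
  w <- quadrature_weights(33L)
  bt <- true_beta_curves(config)
  est <- se <- cov <- matrix(NA_real_, n_replicates, length(gam),
                             dimnames = list(NULL, names(gam)))
  ise <- matrix(NA_real_, n_replicates, length(terms),
                dimnames = list(NULL, terms))
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cohort <- generate_cohort_rng(config)
      fit <- tryCatch(fit_sofr_gaussian(cohort, spec, options),
                      error = function(e)
                        stop(sprintf("replicate %d failed: %s", r,
                                     conditionMessage(e)), call. = FALSE))
      sc <- fit$scalar
      for (v in names(gam)) {
        row <- sc[sc$term == v, ]
        est[r, v] <- row$estimate
        se[r, v] <- row$se
        cov[r, v] <- row$ci_low <= gam[v] && gam[v] <= row$ci_high
      }
      for (term in terms)
        ise[r, term] <- sum(w * (fit$functional[[term]]$beta -
                                   bt[[term]])^2)
    }
  })
  structure(list(
    scalars = data.frame(
      term = names(gam), truth = unname(gam),
      mean_estimate = colMeans(est), bias = colMeans(est) - unname(gam),
      sd_estimate = apply(est, 2, stats::sd), mean_se = colMeans(se),
      coverage = colMeans(cov), row.names = NULL,
      stringsAsFactors = FALSE),
    functional = data.frame(term = terms, mean_ise = colMeans(ise),
                            row.names = NULL, stringsAsFactors = FALSE),
    n_replicates = n_replicates),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> %d replicates\n", x$n_replicates))
  print(format(x$scalars, digits = 3), row.names = FALSE)
  invisible(x)
}
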