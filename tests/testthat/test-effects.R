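test_that("perturbation effects have closed form for constant beta", {
  # beta(t) = c: eta = delta * c * (t_end - t_start)
  for (c0 in c(0.3, -0.2)) {
    fit <- constant_beta_fit(c0)
    for (delta in c(-5, 2)) {
      eff <- perturbation_effect(fit, perturbation("torsion", delta))
      expect_equal(eff$estimate, exp(0.5 * c0 * delta), tolerance = 1e-12)
      expect_identical(eff$scale, "or")
    }
  }
  # beta = 0: OR exactly 1, CI spanning 1
  f0 <- constant_beta_fit(0)
  eff <- perturbation_effect(f0, perturbation("torsion", -5))
  expect_identical(eff$estimate, 1)
  expect_lt(eff$ci_low, 1)
  expect_gt(eff$ci_high, 1)
})

test_that("log-odds perturbations are linear in delta and additive in windows", {
  ch <- small_cohort(n = 60, seed = 15,
                     mortality = list(target_rate = 0.3,
                                      beta_torsion = -0.04,
                                      beta_gls = -0.10))
  fit <- fit_sofr_binomial(ch)
  lo <- function(delta, a = 0.5, b = 1)
    perturbation_effect(fit, perturbation("gls", delta, a, b))$log_estimate
  expect_equal(lo(2 * -5), 2 * lo(-5), tolerance = 1e-12)
  expect_equal(lo(-5, 0.5, 1), lo(-5, 0.5, 0.75) + lo(-5, 0.75, 1),
               tolerance = 1e-12)
  # reversing the shift inverts the odds ratio exactly
  e_neg <- perturbation_effect(fit, perturbation("gls", -5))
  e_pos <- perturbation_effect(fit, perturbation("gls", +5))
  expect_equal(e_neg$estimate, 1 / e_pos$estimate, tolerance = 1e-12)
  expect_gt(e_neg$estimate, 0)
  expect_true(e_neg$ci_low <= e_neg$estimate &
                e_neg$estimate <= e_neg$ci_high)
})

test_that("Gaussian perturbations report mmHg changes", {
  ch <- small_cohort(n = 20, seed = 25)
  fit <- fit_sofr_gaussian(ch)
  eff <- perturbation_effect(fit, perturbation("torsion", 5))
  expect_identical(eff$scale, "mmHg")
  expect_true(eff$ci_low <= eff$estimate & eff$estimate <= eff$ci_high)
})

test_that("invalid perturbation windows are rejected", {
  expect_error(perturbation("gls", -5, 0.9, 0.5), "t_start < t_end")
  expect_error(perturbation("gls", -5, -0.1, 0.5), "t_start")
  expect_error(perturbation("gls", -5, 0.5, 1.2), "t_end")
  fit <- constant_beta_fit(1)
  expect_error(perturbation_effect(fit, perturbation("gls", -5)),
               "unknown functional term")
  # window narrower than one grid step collapses after snapping
  expect_error(perturbation_effect(fit, perturbation("torsion", 1,
                                                     0.50, 0.505)),
               "collapses")
})

test_that("reports are written and their plot data round-trips", {
  ch <- small_cohort(n = 15, seed = 77,
                     mortality = list(target_rate = 0.3,
                                      beta_torsion = -0.04,
                                      beta_gls = -0.10))
  fit_g <- fit_sofr_gaussian(ch)
  fit_b <- fit_sofr_binomial(ch)
  effs <- list(perturbation_effect(fit_b, perturbation("gls", -5)))
  out <- withr::local_tempdir()
  files <- render_report(list(sbp = fit_g, mortality = fit_b), effs, out)
  expect_true(all(file.exists(files)))

  # coefficients CSV mirrors the scalar covariate rows
  tab <- read.csv(file.path(out, "sbp_coefficients.csv"))
  cov <- fit_g$scalar[fit_g$scalar$group == "covariate", ]
  expect_identical(tab$term, cov$term)
  expect_equal(tab$coefficient, cov$estimate)

  # beta(t) CSV round-trips the grid evaluation
  df <- read.csv(file.path(out, "sbp_beta_torsion.csv"))
  expect_equal(df$beta, fit_g$functional$torsion$beta, tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "effects.csv")))

  # tables only when no effects are given
  out2 <- withr::local_tempdir()
  files2 <- render_report(fit_g, list(), out2)
  expect_false(file.exists(file.path(out2, "effects.csv")))
  expect_true(any(grepl("coefficients", files2)))
})

test_that("fits survive a JSON round-trip for downstream inference", {
  ch <- small_cohort(n = 40, seed = 31,
                     mortality = list(target_rate = 0.3,
                                      beta_torsion = -0.04,
                                      beta_gls = -0.10))
  fit <- fit_sofr_binomial(ch)
  p <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, p)
  back <- read_fit_json(p)
  expect_equal(back$functional$gls$beta, fit$functional$gls$beta,
               tolerance = 1e-12)
  expect_equal(back$functional$gls$Vb, unname(fit$functional$gls$Vb),
               tolerance = 1e-12)
  e1 <- perturbation_effect(fit, perturbation("gls", -5))
  e2 <- perturbation_effect(back, perturbation("gls", -5))
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)
  expect_equal(e1$ci_low, e2$ci_low, tolerance = 1e-8)
  expect_equal(global_pvalue(back, "gls"), global_pvalue(fit, "gls"),
               tolerance = 1e-4)
})
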