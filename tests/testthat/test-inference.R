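test_that("pointwise bands are centered, ordered and monotone in level", {
  ch <- small_cohort(n = 20, seed = 6)
  fit <- fit_sofr_gaussian(ch)
  b95 <- pointwise_band(fit, "torsion", 0.95)
  b68 <- pointwise_band(fit, "torsion", 0.6827)
  expect_true(all(b95$lower <= b95$upper))
  expect_equal((b95$lower + b95$upper) / 2, b95$estimate)
  # narrower level strictly inside
  expect_true(all(b68$lower > b95$lower))
  expect_true(all(b68$upper < b95$upper))
  expect_error(pointwise_band(fit, "nope"), "unknown functional term")
})

test_that("pointwise SE scales with the residual noise at fixed design", {
  # same seed, same covariates/curves; residual SD halved exactly halves
  # the noise realization, so at fixed penalties SE(t) ratio -> 1/2
  cfg1 <- null_config(n = 60, sigma_b = 0, sigma_eps = 10)
  cfg2 <- null_config(n = 60, sigma_b = 0, sigma_eps = 5)
  ch1 <- generate_cohort(cfg1, 19)
  ch2 <- generate_cohort(cfg2, 19)
  expect_identical(ch1$curves$torsion, ch2$curves$torsion)
  opts <- reduced_options(random_intercept = FALSE,
                          fixed_lambda = c(torsion = 100))
  f1 <- fit_sofr_gaussian(ch1, options = opts)
  f2 <- fit_sofr_gaussian(ch2, options = opts)
  ratio <- f2$functional$torsion$se / f1$functional$torsion$se
  expect_true(all(abs(ratio - 0.5) < 0.05))
})

test_that("the global test is invariant to rescaling the covariate", {
  ch <- small_cohort(n = 25, seed = 23)
  p1 <- global_pvalue(fit_sofr_gaussian(ch, options = reduced_options()),
                      "torsion")
  ch2 <- ch
  ch2$curves$torsion <- ch2$curves$torsion * 3
  p2 <- global_pvalue(fit_sofr_gaussian(ch2, options = reduced_options()),
                      "torsion")
  expect_true(p1 >= 0 && p1 <= 1)
  expect_equal(p1, p2, tolerance = 1e-3)
})

test_that("a strong functional effect is detected with tiny p-values", {
  cfg <- null_config(n = 70)
  cfg$sbp$beta_torsion <- 40   # signal-to-noise well above 5
  set.seed(31)
  pv <- replicate(20, {
    ch <- generate_cohort(cfg, sample.int(2^31 - 2, 1))
    fit <- fit_sofr_gaussian(ch, options = reduced_options())
    global_pvalue(fit, "torsion")
  })
  expect_gte(mean(pv < 1e-3), 0.9)
})

test_that("band and global test agree on strong effects", {
  cfg <- null_config(n = 70)
  cfg$sbp$beta_torsion <- 40
  set.seed(37)
  for (r in 1:5) {
    ch <- generate_cohort(cfg, sample.int(2^31 - 2, 1))
    fit <- fit_sofr_gaussian(ch, options = reduced_options())
    bd <- pointwise_band(fit, "torsion")
    if (mean(bd$lower > 0 | bd$upper < 0) > 0.5)
      expect_lt(global_pvalue(fit, "torsion"), 0.05)
  }
})

test_that("the cluster bootstrap is seed-deterministic", {
  ch <- small_cohort(n = 15, seed = 3)
  opts <- reduced_options()
  b1 <- bootstrap_band(ch, basis_spec(), "torsion", B = 60, seed = 7,
                       options = opts)
  b2 <- bootstrap_band(ch, basis_spec(), "torsion", B = 60, seed = 7,
                       options = opts)
  b3 <- bootstrap_band(ch, basis_spec(), "torsion", B = 60, seed = 8,
                       options = opts)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_false(identical(b1$lower, b3$lower))
  expect_identical(b1$method, "bootstrap")
  expect_true(all(b1$lower <= b1$upper))
  expect_error(bootstrap_band(ch, basis_spec(), "torsion", B = 10,
                              seed = 1), "B >= 50")
})

test_that("the bootstrap band brackets a null effect", {
  # true beta is 0: in most replicated cohorts the percentile band should
  # contain 0 over most of the grid
  cfg <- null_config(n = 40)
  ok <- vapply(1:8, function(r) {
    ch <- generate_cohort(cfg, 100 + r)
    bb <- bootstrap_band(ch, basis_spec(), "torsion", B = 60, seed = r,
                         options = reduced_options())
    mean(bb$lower <= 0 & 0 <= bb$upper) >= 0.9
  }, logical(1))
  expect_gte(mean(ok), 0.75)
})
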