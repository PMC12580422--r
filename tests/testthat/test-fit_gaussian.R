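test_that("the fixed-penalty fit equals the closed-form generalized ridge", {
  ch <- small_cohort(n = 20, seed = 11)
  fl <- c(torsion = 50, gls = 5, rv_free_wall = 500, patient = 3)
  fit <- fit_sofr_gaussian(ch, options = sofr_options(fixed_lambda = fl))

  # independent oracle: rebuild the augmented design and solve directly
  b <- build_basis(basis_spec())
  w <- quadrature_weights(33)
  sbp <- ch$sbp
  obs <- match(sbp$subject_id, ch$patients$subject_id)
  X <- cbind(1, sapply(2:7, function(j) as.numeric(sbp$occasion == j)),
             as.matrix(ch$patients[obs, c("age", "sex", "hypertension",
                                          "diabetes", "dialysis_vintage",
                                          "ultrafiltrate", "ivc_diameter",
                                          "lv_mass_indexed")]))
  J <- lapply(c("torsion", "gls", "rv_free_wall"), function(m) {
    M <- ch$curves[[m]]
    Mc <- sweep(M, 2, colMeans(M))
    ((Mc * rep(w, each = nrow(Mc))) %*% b$B)[obs, ]
  })
  Zb <- outer(obs, seq_len(20), `==`) * 1
  C <- cbind(X, J[[1]], J[[2]], J[[3]], Zb)
  S <- matrix(0, ncol(C), ncol(C))
  for (k in 1:3) {
    ii <- 15 + (k - 1) * 9 + 1:9
    S[ii, ii] <- fl[k] * b$P
  }
  ii <- 42 + 1:20
  S[ii, ii] <- fl["patient"] * diag(20)
  beta_oracle <- solve(crossprod(C) + S, crossprod(C, sbp$sbp))
  expect_lt(max(abs(fit$coefficients - beta_oracle)), 1e-8)
})

test_that("a constant response gives an intercept-only fit", {
  ch <- small_cohort(n = 20, seed = 3)
  ch$sbp$sbp <- 100
  fit <- fit_sofr_gaussian(ch)
  expect_equal(fit$scalar$estimate[1], 100, tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-6)
  expect_equal(fit$variance_explained, 1)
})

test_that("the multilevel REML fit agrees with lme4 on the scalar model", {
  ch <- small_cohort(n = 40, seed = 21)
  fit <- fit_sofr_gaussian(ch, options = sofr_options(
    functional_terms = character(0)))
  sbp <- ch$sbp
  obs <- match(sbp$subject_id, ch$patients$subject_id)
  df <- data.frame(y = sbp$sbp, occ = factor(sbp$occasion),
                   ch$patients[obs, c("age", "sex", "hypertension",
                                      "diabetes", "dialysis_vintage",
                                      "ultrafiltrate", "ivc_diameter",
                                      "lv_mass_indexed")],
                   id = sbp$subject_id)
  m <- lme4::lmer(
    y ~ occ + age + sex + hypertension + diabetes + dialysis_vintage +
      ultrafiltrate + ivc_diameter + lv_mass_indexed + (1 | id),
    data = df, REML = TRUE)
  fe <- lme4::fixef(m)
  keep <- c("age", "sex", "ultrafiltrate", "ivc_diameter")
  expect_equal(unname(fe[keep]),
               fit$scalar$estimate[match(keep, fit$scalar$term)],
               tolerance = 1e-5)
  expect_equal(fit$sigma_eps, sigma(m), tolerance = 1e-5)
  expect_equal(fit$sigma_b,
               unname(attr(lme4::VarCorr(m)$id, "stddev")),
               tolerance = 1e-4)
})

test_that("REML smoothing selection agrees with mgcv on the full model", {
  ch <- small_cohort(n = 50, seed = 33)
  fit <- fit_sofr_gaussian(ch)
  b <- build_basis(basis_spec())
  w <- quadrature_weights(33)
  sbp <- ch$sbp
  obs <- match(sbp$subject_id, ch$patients$subject_id)
  mk <- function(m) {
    M <- sweep(ch$curves[[m]], 2, colMeans(ch$curves[[m]]))
    (M * rep(w, each = nrow(M)))[obs, ]
  }
  df <- data.frame(y = sbp$sbp, occ = factor(sbp$occasion),
                   ch$patients[obs, c("age", "sex", "hypertension",
                                      "diabetes", "dialysis_vintage",
                                      "ultrafiltrate", "ivc_diameter",
                                      "lv_mass_indexed")],
                   id = factor(obs))
  df$Xtor <- mk("torsion"); df$Xgls <- mk("gls"); df$Xrv <- mk("rv_free_wall")
  df$Tmat <- matrix(cycle_grid(33), nrow(sbp), 33, byrow = TRUE)
  g <- mgcv::gam(
    y ~ occ + age + sex + hypertension + diabetes + dialysis_vintage +
      ultrafiltrate + ivc_diameter + lv_mass_indexed +
      s(Tmat, by = Xtor, bs = "ps", k = 9, m = c(2, 2)) +
      s(Tmat, by = Xgls, bs = "ps", k = 9, m = c(2, 2)) +
      s(Tmat, by = Xrv, bs = "ps", k = 9, m = c(2, 2)) +
      s(id, bs = "re"),
    data = df, method = "REML")
  keep <- c("age", "ultrafiltrate", "ivc_diameter", "lv_mass_indexed")
  est <- fit$scalar$estimate[match(keep, fit$scalar$term)]
  se <- fit$scalar$se[match(keep, fit$scalar$term)]
  expect_lt(max(abs(est - unname(coef(g)[keep])) / se), 0.02)
  expect_equal(fit$sigma_eps, sqrt(g$sig2), tolerance = 1e-3)
})

test_that("an infinite penalty removes a functional term exactly", {
  ch <- small_cohort(n = 12, seed = 5)
  fit <- fit_sofr_gaussian(ch, options = sofr_options(
    fixed_lambda = c(gls = Inf)))
  expect_equal(fit$functional$gls$beta, rep(0, 33))
  expect_equal(global_pvalue(fit, "gls"), 1)
})

test_that("degenerate inputs raise informative errors", {
  ch <- small_cohort(n = 10, seed = 9)
  ch$patients$diabetes <- 0
  expect_error(fit_sofr_gaussian(ch), "rank deficient.*diabetes")
  ch2 <- small_cohort(n = 10, seed = 9)
  ch2$sbp$sbp <- NA_real_
  expect_error(fit_sofr_gaussian(ch2), "no SBP")
})

test_that("with vanishing residual noise the fit interpolates patient means", {
  cfg <- null_config(n = 20, sigma_b = 8, sigma_eps = 0.05)
  ch <- generate_cohort(cfg, 13)
  fit <- fit_sofr_gaussian(ch, options = reduced_options())
  # fitted values (fixed + random) reproduce the data: shrinkage vanishes
  expect_lt(fit$sigma_eps, 0.2)
  expect_gt(fit$variance_explained, 0.999)
  # random-intercept predictions track patient mean deviations and are
  # essentially unshrunk at this noise level
  expect_gt(stats::cor(fit$ranef,
                       tapply(ch$sbp$sbp, ch$sbp$subject_id,
                              mean)[names(fit$ranef)]), 0.95)
  expect_gt(stats::sd(fit$ranef), 4)
})

test_that("fit results satisfy their structural invariants", {
  ch <- small_cohort(n = 15, seed = 44)
  fit <- fit_sofr_gaussian(ch)
  expect_true(all(fit$scalar$ci_low <= fit$scalar$estimate))
  expect_true(all(fit$scalar$estimate <= fit$scalar$ci_high))
  expect_gte(fit$sigma_b, 0)
  expect_gt(fit$sigma_eps, 0)
  expect_true(is.finite(fit$aic))
  expect_true(fit$variance_explained >= 0 && fit$variance_explained <= 1)
  for (f in fit$functional) {
    expect_length(f$beta, 33)
    expect_true(all(f$se > 0))
    # grid evaluation consistent with basis x coefficients
    B <- build_basis(fit$spec)$B
    expect_equal(f$beta, drop(B %*% f$coefs), tolerance = 1e-10)
  }
})
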