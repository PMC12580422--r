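# Penalized scalar-on-function regression engine.
#
# Both families share one augmented-ridge formulation: the design holds
# unpenalized columns (intercept, occasion indicators, scalar covariates)
# plus penalized blocks (one per functional term: integrated
# curve-times-basis columns with a difference penalty; plus, for the
# Gaussian model, patient indicator columns with a ridge penalty, i.e.
# the random intercept). Smoothing parameters and variance components are
# the block penalty weights, selected by (Laplace) REML.

#' Fitting options for the SBP model
#'
#' @param functional_terms Functional covariates to include; default all
#'   of `torsion`, `gls`, `rv_free_wall`.
#' @param scalar_terms Scalar covariates; default the full Table-style
#'   covariate set (age, sex, hypertension, diabetes, dialysis_vintage,
#'   ultrafiltrate, ivc_diameter, lv_mass_indexed).
#' @param occasion_effects Model the 7 measurement occasions as fixed
#'   indicator effects (default `TRUE`), capturing the systematic SBP
#'   decline over a dialysis session.
#' @param random_intercept Include the patient-level random intercept
#'   (default `TRUE`).
#' @param fixed_lambda Optional named numeric vector fixing smoothing
#'   parameters instead of selecting them by REML. Names are functional
#'   term names or `"patient"` for the random-intercept block
#'   (`lambda_patient = sigma_eps^2 / sigma_b^2`). Value `Inf` removes
#'   the block entirely (coefficients exactly zero).
#' @return A list of options for [fit_sofr_gaussian()].
#' @export
sofr_options <- function(functional_terms = FUNCTIONAL_TERMS,
                         scalar_terms = SCALAR_COVARIATES,
                         occasion_effects = TRUE,
                         random_intercept = TRUE,
                         fixed_lambda = NULL) {
  stopifnot(all(functional_terms %in% FUNCTIONAL_TERMS),
            all(scalar_terms %in% SCALAR_COVARIATES))
  list(functional_terms = functional_terms, scalar_terms = scalar_terms,
       occasion_effects = occasion_effects,
       random_intercept = random_intercept, fixed_lambda = fixed_lambda)
}

# ---- shared internals ------------------------------------------------------

# Eigen summaries of a unit penalty matrix needed by the REML criterion.
penalty_summary <- function(P, null_dim) {
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  rank <- ncol(P) - null_dim
  list(rank = rank, log_pdet = sum(log(ev[seq_len(rank)])))
}

# blocks: list of list(name, Z (n x q), P (q x q unit penalty), rank,
# log_pdet, null_dim). Returns assembled design + bookkeeping.
assemble_design <- function(X, blocks, fixed_lambda = NULL) {
  fixed_lambda <- fixed_lambda %||% numeric(0)
  dropped <- character(0)
  keep <- vapply(blocks, function(b) {
    !(b$name %in% names(fixed_lambda) && is.infinite(fixed_lambda[b$name]))
  }, logical(1))
  dropped <- vapply(blocks[!keep], `[[`, character(1), "name")
  blocks <- blocks[keep]
  p0 <- ncol(X)
  C <- X
  idx <- list()
  for (b in blocks) {
    idx[[b$name]] <- p0 + seq_len(ncol(b$Z))
    C <- cbind(C, b$Z)
    p0 <- p0 + ncol(b$Z)
  }
  fixed <- rep(NA_real_, length(blocks))
  names(fixed) <- vapply(blocks, `[[`, character(1), "name")
  common <- intersect(names(fixed), names(fixed_lambda))
  fixed[common] <- fixed_lambda[common]
  list(C = C, blocks = blocks, idx = idx, p_unpen = ncol(X),
       fixed = fixed, dropped = dropped)
}

# Add lambda_j * P_j into a copy of M over each block's columns.
add_penalty <- function(M, des, lambda) {
  for (j in seq_along(des$blocks)) {
    cols <- des$idx[[des$blocks[[j]]$name]]
    M[cols, cols] <- M[cols, cols] + lambda[j] * des$blocks[[j]]$P
  }
  M
}

# Upper-triangular factor of a term's design block (with its pivot),
# used to put Wald tests on the fitted-value scale.
block_qr <- function(Z) {
  qrx <- qr(Z)
  R <- qr.R(qrx)
  attr(R, "pivot") <- qrx$pivot
  R
}

# Cholesky with escalating diagonal jitter; the augmented system can be
# numerically semidefinite when a selected penalty sits at its floor.
safe_chol <- function(A) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  jit <- 1e-10 * mean(diag(A))
  while (is.null(R) && jit < 1e-2 * mean(diag(A))) {
    R <- tryCatch(chol(A + jit * diag(nrow(A))), error = function(e) NULL)
    jit <- jit * 100
  }
  if (is.null(R)) stop("augmented normal equations are singular",
                       call. = FALSE)
  R
}

penalty_quadform <- function(des, lambda, beta) {
  sum(vapply(seq_along(des$blocks), function(j) {
    cols <- des$idx[[des$blocks[[j]]$name]]
    bj <- beta[cols]
    lambda[j] * sum(bj * (des$blocks[[j]]$P %*% bj))
  }, numeric(1)))
}

log_pdet_S <- function(des, lambda) {
  sum(vapply(seq_along(des$blocks), function(j) {
    b <- des$blocks[[j]]
    b$rank * log(lambda[j]) + b$log_pdet
  }, numeric(1)))
}

# Per-block scale factors putting the penalty on the design's scale, so
# the log-smoothing-parameter search is well conditioned around 0.
penalty_scales <- function(des, CtC) {
  vapply(des$blocks, function(b) {
    cols <- des$idx[[b$name]]
    s <- sqrt(sum(CtC[cols, cols]^2)) / sqrt(sum(b$P^2))
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))
}

# Minimize `neg` over the log-lambdas of blocks without a fixed lambda.
# The search runs in scaled units (lambda = exp(rho) * scale) within a
# soft-bounded box; reported lambdas are on the raw penalty scale.
optimize_rho <- function(des, neg, scale = rep(1, length(des$blocks))) {
  free <- which(is.na(des$fixed))
  lam <- des$fixed
  if (!length(free)) return(list(lambda = lam, convergence = 0L))
  make_lam <- function(rho) {
    lam[free] <- exp(pmin(pmax(rho, -18), 18)) * scale[free]
    lam
  }
  barrier <- function(rho) 10 * sum(pmax(abs(rho) - 18, 0)^2)
  f <- function(rho) neg(make_lam(rho)) + barrier(rho)
  if (length(free) == 1L) {
    opt <- stats::optimize(f, interval = c(-18, 18), tol = 1e-8)
    return(list(lambda = make_lam(opt$minimum), convergence = 0L))
  }
  par <- rep(0, length(free))
  opt <- NULL
  for (try in 1:3) {
    opt <- stats::optim(par, f, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    par <- opt$par
    if (opt$convergence == 0L) break
  }
  if (opt$convergence != 0L) {
    # Nelder-Mead can report simplex degeneracy at a flat optimum; accept
    # the point when the numerical gradient is effectively zero
    h <- 1e-4
    g <- vapply(seq_along(opt$par), function(k) {
      e <- opt$par; e[k] <- e[k] + h
      (f(e) - opt$value) / h
    }, numeric(1))
    if (sqrt(sum(g^2)) > 0.05)
      stop(sprintf(
        "smoothing-parameter selection failed to converge (code %d, gradient norm %.3g)",
        opt$convergence, sqrt(sum(g^2))), call. = FALSE)
  }
  list(lambda = make_lam(opt$par), convergence = 0L)
}

check_scalar_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("scalar design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "),
         " (constant or collinear covariates?)", call. = FALSE)
  }
  invisible(TRUE)
}

# Build the functional-term penalized blocks at patient level and expand
# them to observation rows via `row_of_patient` (identity for binomial).
functional_blocks <- function(data, terms, basis, row_of_patient = NULL) {
  w <- quadrature_weights(nrow(basis$B))
  ps <- penalty_summary(basis$P, basis$null_dim)
  lapply(terms, function(term) {
    J <- functional_design(data$curves[[term]], basis, w)
    ctr <- attr(J, "center")
    Z <- if (is.null(row_of_patient)) J else J[row_of_patient, , drop = FALSE]
    list(name = term, Z = unname(Z), P = basis$P, rank = ps$rank,
         log_pdet = ps$log_pdet, null_dim = basis$null_dim, center = ctr)
  })
}

functional_results <- function(des, basis, beta, Vb, edf_vec, lambda,
                               units) {
  out <- list()
  for (b in des$blocks) {
    if (!is.null(b$center)) {       # functional blocks carry a center curve
      cols <- des$idx[[b$name]]
      coefs <- beta[cols]
      Vk <- Vb[cols, cols, drop = FALSE]
      BV <- basis$B %*% Vk
      out[[b$name]] <- list(
        term = b$name, coefs = coefs, grid = cycle_grid(nrow(basis$B)),
        beta = as.numeric(basis$B %*% coefs),
        se = sqrt(pmax(rowSums(BV * basis$B), 0)),
        Vb = Vk, edf = sum(edf_vec[cols]),
        lambda = lambda[b$name], center = b$center, units = units,
        design_R = block_qr(b$Z))
    }
  }
  # terms removed via lambda = Inf are reported as exactly zero
  for (nm in des$dropped) {
    out[[nm]] <- list(term = nm, coefs = rep(0, basis$spec$n_basis),
                      grid = cycle_grid(nrow(basis$B)),
                      beta = rep(0, nrow(basis$B)),
                      se = rep(0, nrow(basis$B)),
                      Vb = matrix(0, basis$spec$n_basis, basis$spec$n_basis),
                      edf = 0, lambda = Inf, center = NULL, units = units)
  }
  out
}

scalar_table <- function(beta, Vb, cols, groups, level = 0.95) {
  est <- beta[cols]
  se <- sqrt(diag(Vb)[cols])
  z <- est / se
  zc <- stats::qnorm((1 + level) / 2)
  data.frame(term = names(cols), group = groups, estimate = est, se = se,
             ci_low = est - zc * se, ci_high = est + zc * se,
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- Gaussian multilevel SBP model ----------------------------------------

#' Multilevel scalar-on-function regression for intradialytic SBP
#'
#' Fits, for patient i at session s and occasion j,
#' \deqn{SBP_{isj} = \alpha + occ_j + z_i^\top\gamma +
#'   \sum_m \int_0^1 \beta_m(t) X_{im}(t)\,dt + b_i + \varepsilon_{isj}}
#' with patient random intercepts \eqn{b_i \sim N(0, \sigma_b^2)} and
#' residuals \eqn{\varepsilon \sim N(0, \sigma_\varepsilon^2)}. Functional
#' coefficients are penalized B-splines; integrals use trapezoid
#' quadrature on the 33-point grid; curves are centered at the sample
#' mean curve. Smoothing parameters and variance components are selected
#' jointly by exact REML in the augmented-ridge formulation; at fixed
#' penalties the estimate is the closed-form generalized-ridge solution.
#'
#' @param data A [cohort_data()] object (missing SBP entries are dropped
#'   row-wise).
#' @param spec A [basis_spec()].
#' @param options See [sofr_options()].
#' @return An object of class `sofr_fit` with elements `family`,
#'   `scalar` (coefficient table with Wald 95% CIs and p-values),
#'   `functional` (per-term coefficient function: grid evaluation,
#'   pointwise SE, penalized-coefficient covariance, effective df,
#'   smoothing parameter), `sigma_b`, `sigma_eps`, `variance_explained`,
#'   `lambda`, `loglik`, `aic`, `edf_total`, `ranef`.
#' @export
fit_sofr_gaussian <- function(data, spec = basis_spec(),
                              options = sofr_options()) {
  stopifnot(inherits(data, "cohort_data"))
  pt <- data$patients
  sbp <- data$sbp[!is.na(data$sbp$sbp), , drop = FALSE]
  if (!nrow(sbp)) stop("no SBP observations", call. = FALSE)
  if (length(unique(sbp$subject_id)) < 2L)
    stop("need at least 2 patients with SBP data", call. = FALSE)
  obs_of <- match(sbp$subject_id, pt$subject_id)
  y <- sbp$sbp
  n <- length(y)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  groups <- "intercept"
  if (isTRUE(options$occasion_effects)) {
    for (j in 2:7) {
      X <- cbind(X, as.numeric(sbp$occasion == j))
      colnames(X)[ncol(X)] <- paste0("occasion_", j)
      groups <- c(groups, "occasion")
    }
  }
  for (v in options$scalar_terms) {
    X <- cbind(X, pt[[v]][obs_of])
    colnames(X)[ncol(X)] <- v
    groups <- c(groups, "covariate")
  }
  check_scalar_rank(X)

  basis <- build_basis(spec)
  blocks <- functional_blocks(data, options$functional_terms, basis,
                              row_of_patient = obs_of)
  if (isTRUE(options$random_intercept)) {
    Zb <- matrix(0, n, nrow(pt))
    Zb[cbind(seq_len(n), obs_of)] <- 1
    blocks <- c(blocks, list(list(
      name = "patient", Z = Zb, P = diag(nrow(pt)), rank = nrow(pt),
      log_pdet = 0, null_dim = 0L, center = NULL)))
  }
  des <- assemble_design(X, blocks, options$fixed_lambda)

  C <- des$C
  CtC <- crossprod(C)
  Cty <- drop(crossprod(C, y))
  yty <- sum(y^2)
  Mp <- des$p_unpen +
    sum(vapply(des$blocks, `[[`, integer(1), "null_dim"))

  neg_reml <- function(lambda) {
    A <- add_penalty(CtC, des, lambda)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    beta <- backsolve(R, forwardsolve(t(R), Cty))
    Dp <- max(yty - sum(beta * Cty), 1e-12)
    0.5 * (n - Mp) * log(Dp) + sum(log(diag(R))) -
      0.5 * log_pdet_S(des, lambda)
  }
  opt <- optimize_rho(des, neg_reml, penalty_scales(des, CtC))
  lambda <- opt$lambda

  A <- add_penalty(CtC, des, lambda)
  R <- safe_chol(A)
  beta <- backsolve(R, forwardsolve(t(R), Cty))
  Dp <- max(yty - sum(beta * Cty), 1e-12)
  sigma2 <- Dp / (n - Mp)
  Ainv <- chol2inv(R)
  Vb <- sigma2 * Ainv
  edf_vec <- rowSums(Ainv * CtC)
  fitted <- drop(C %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  ve <- if (tss <= 1e-10) 1 else 1 - rss / tss
  edf_total <- sum(edf_vec)
  loglik <- -n / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)

  cols <- seq_len(des$p_unpen)
  names(cols) <- colnames(X)
  sc <- scalar_table(beta, Vb, cols, groups)
  sigma_b <- if ("patient" %in% names(lambda))
    sqrt(sigma2 / lambda["patient"]) else 0
  ranef <- if ("patient" %in% names(des$idx)) {
    b <- beta[des$idx$patient]; names(b) <- pt$subject_id; b
  } else NULL

  structure(list(
    family = "gaussian", scalar = sc,
    functional = functional_results(des, basis, beta, Vb, edf_vec, lambda,
                                    units = "mmHg per curve-unit"),
    lambda = lambda[setdiff(names(lambda), "patient")],
    sigma_b = unname(sigma_b), sigma_eps = sqrt(sigma2),
    variance_explained = ve, loglik = loglik,
    aic = -2 * loglik + 2 * (edf_total + 1),
    edf_total = edf_total, deviance = rss,
    n_obs = n, n_patients = nrow(pt), ranef = ranef,
    coefficients = beta, Vb = Vb, spec = spec, options = options),
    class = "sofr_fit")
}

# ---- Binomial mortality model ---------------------------------------------

#' Binomial scalar-on-function regression for mortality
#'
#' Fits, one row per patient,
#' \deqn{\mathrm{logit}\,P(death_i = 1) = \alpha +
#'   \sum_m \int_0^1 \beta_m(t) X_{im}(t)\,dt}
#' by penalized iteratively reweighted least squares, with smoothing
#' parameters selected by Laplace-approximate REML on the working model.
#' Coefficient functions are on the log-odds scale. The default
#' predictors are the GLS and torsion curves with no scalar adjustment
#' (appropriate when events are few); `adjust_age = TRUE` adds age as a
#' sensitivity analysis.
#'
#' @param data A [cohort_data()] object with at least one event and one
#'   non-event.
#' @param spec A [basis_spec()].
#' @param functional_terms Functional predictors; default
#'   `c("gls", "torsion")`.
#' @param adjust_age Add the scalar age covariate (default `FALSE`).
#' @param fixed_lambda Optional named fixed smoothing parameters; value
#'   `0` gives the unpenalized maximum-likelihood fit, `Inf` removes the
#'   term (see [sofr_options()]).
#' @return An object of class `sofr_fit` (family `"binomial"`) with
#'   `deviance` and effective-dof `aic`.
#' @export
fit_sofr_binomial <- function(data, spec = basis_spec(),
                              functional_terms = c("gls", "torsion"),
                              adjust_age = FALSE, fixed_lambda = NULL) {
  stopifnot(inherits(data, "cohort_data"),
            all(functional_terms %in% FUNCTIONAL_TERMS))
  y <- data$patients$death
  n <- length(y)
  if (sum(y) < 1 || sum(1 - y) < 1)
    stop("mortality model needs at least one event and one non-event",
         call. = FALSE)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  groups <- "intercept"
  if (isTRUE(adjust_age)) {
    X <- cbind(X, age = data$patients$age)
    groups <- c(groups, "covariate")
  }
  check_scalar_rank(X)
  basis <- build_basis(spec)
  blocks <- functional_blocks(data, functional_terms, basis)
  des <- assemble_design(X, blocks, fixed_lambda)
  C <- des$C

  warm <- NULL  # warm start shared across REML evaluations
  pirls <- function(lambda) {
    beta <- rep(0, ncol(C))
    if (!is.null(warm) && length(warm) == ncol(C)) {
      eta <- drop(C %*% warm)
      if (max(abs(eta)) < 25) { beta <- warm; mu <- stats::plogis(eta) }
      else { mu <- (y + 0.5) / 2; eta <- stats::qlogis(mu) }
    } else {
      mu <- (y + 0.5) / 2
      eta <- stats::qlogis(mu)
    }
    crit_old <- Inf
    for (it in seq_len(200L)) {
      W <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / W
      A <- add_penalty(crossprod(C, W * C), des, lambda)
      R <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(R)) return(NULL)
      beta <- backsolve(R, forwardsolve(t(R), drop(crossprod(C, W * z))))
      eta <- drop(C %*% beta)
      if (max(abs(eta)) > 30)
        stop("complete separation detected: fitted log-odds diverge",
             call. = FALSE)
      mu <- stats::plogis(eta)
      dev <- sum(stats::binomial()$dev.resids(y, mu, rep(1, n)))
      pen <- penalty_quadform(des, lambda, beta)
      crit <- dev + pen
      if (abs(crit - crit_old) < 1e-11 * (abs(crit) + 0.1)) break
      crit_old <- crit
    }
    warm <<- beta
    W <- pmax(mu * (1 - mu), 1e-10)
    CtWC <- crossprod(C, W * C)
    A <- add_penalty(CtWC, des, lambda)
    R <- safe_chol(A)
    list(beta = beta, eta = eta, mu = mu, dev = dev, pen = pen,
         A = A, R = R, CtWC = CtWC)
  }

  neg_reml <- function(lambda) {
    ft <- tryCatch(pirls(lambda), error = function(e) NULL)
    if (is.null(ft)) return(1e10)
    0.5 * (ft$dev + ft$pen) + sum(log(diag(ft$R))) -
      0.5 * log_pdet_S(des, lambda)
  }
  opt <- optimize_rho(des, neg_reml,
                      penalty_scales(des, 0.25 * crossprod(C)))
  lambda <- opt$lambda
  warm <- NULL   # cold-start the final fit so it is path-independent
  ft <- pirls(lambda)
  if (is.null(ft)) stop("penalized IRLS failed", call. = FALSE)

  Ainv <- chol2inv(ft$R)
  Vb <- Ainv                       # phi = 1 for binomial
  edf_vec <- rowSums(Ainv * ft$CtWC)
  edf_total <- sum(edf_vec)
  cols <- seq_len(des$p_unpen)
  names(cols) <- colnames(X)

  structure(list(
    family = "binomial",
    scalar = scalar_table(ft$beta, Vb, cols, groups),
    functional = functional_results(des, basis, ft$beta, Vb, edf_vec,
                                    lambda, units = "log-odds per curve-unit"),
    lambda = lambda,
    sigma_b = NA_real_, sigma_eps = NA_real_,
    variance_explained = NA_real_,
    loglik = -ft$dev / 2, aic = ft$dev + 2 * edf_total,
    edf_total = edf_total, deviance = ft$dev,
    n_obs = n, n_patients = n, ranef = NULL,
    coefficients = ft$beta, Vb = Vb, spec = spec,
    options = list(functional_terms = functional_terms,
                   adjust_age = adjust_age, fixed_lambda = fixed_lambda)),
    class = "sofr_fit")
}

#' @export
print.sofr_fit <- function(x, ...) {
  cat(sprintf("<sofr_fit> family %s, %d obs / %d patients\n",
              x$family, x$n_obs, x$n_patients))
  if (x$family == "gaussian")
    cat(sprintf("  sigma_b %.2f, sigma_eps %.2f, variance explained %.1f%%\n",
                x$sigma_b, x$sigma_eps, 100 * x$variance_explained))
  cat(sprintf("  AIC %.1f, total edf %.1f\n", x$aic, x$edf_total))
  cov <- x$scalar[x$scalar$group == "covariate", , drop = FALSE]
  if (nrow(cov)) {
    cat("  scalar covariates:\n")
    print(format(cov[, c("term", "estimate", "ci_low", "ci_high", "p")],
                 digits = 3), row.names = FALSE)
  }
  for (f in x$functional)
    cat(sprintf("  beta_%s(t): edf %.2f, lambda %.3g\n",
                f$term, f$edf, f$lambda))
  invisible(x)
}
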