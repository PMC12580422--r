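# Frequentist inference for functional coefficients.

get_functional <- function(fit, term) {
  stopifnot(inherits(fit, "sofr_fit"))
  if (!term %in% names(fit$functional))
    stop(sprintf("unknown functional term '%s'; available: %s", term,
                 paste(names(fit$functional), collapse = ", ")),
         call. = FALSE)
  fit$functional[[term]]
}

#' Pointwise Wald confidence band for a functional coefficient
#'
#' \eqn{\hat\beta(t_l) \pm z_{(1+level)/2}\,SE(t_l)} with the pointwise
#' standard error propagated from the Bayesian covariance of the
#' penalized basis coefficients through the basis matrix.
#'
#' @param fit A `sofr_fit`.
#' @param term Functional term name.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return An object of class `confidence_band` with fields `t`,
#'   `estimate`, `lower`, `upper`, `level`, `method`, `term`.
#' @export
pointwise_band <- function(fit, term, level = 0.95) {
  stopifnot(level > 0, level < 1)
  f <- get_functional(fit, term)
  z <- stats::qnorm((1 + level) / 2)
  structure(list(t = f$grid, estimate = f$beta,
                 lower = f$beta - z * f$se, upper = f$beta + z * f$se,
                 level = level, method = "wald", term = term),
            class = "confidence_band")
}

#' @export
print.confidence_band <- function(x, ...) {
  cat(sprintf("<confidence_band> %s, %s, level %.3f; excludes 0 at %d/%d grid points\n",
              x$term, x$method, x$level,
              sum(x$lower > 0 | x$upper < 0), length(x$t)))
  invisible(x)
}

#' Global Wald test of a functional coefficient
#'
#' Tests \eqn{H_0: \beta_{term}(t) \equiv 0} with a Wald-type statistic
#' on the fitted-value scale: with `R` the triangular factor of the
#' term's design block, the statistic is
#' \eqn{(R\hat\theta)^\top (R V R^\top)_r^{-} (R\hat\theta)}, the
#' covariance pseudo-inverse truncated at the rank given by the rounded
#' effective degrees of freedom of the term. Working on \eqn{R\theta}
#' weights coefficient directions by how strongly the observed curves
#' identify them, which is what gives the test power against effects the
#' design can actually express. The p-value is the upper chi-square tail
#' at the truncation rank.
#'
#' @param fit A `sofr_fit`.
#' @param term Functional term name.
#' @return p-value in \eqn{[0, 1]}.
#' @export
global_pvalue <- function(fit, term) {
  f <- get_functional(fit, term)
  if (is.infinite(f$lambda)) return(1)       # term removed: beta is 0
  R <- f$design_R
  if (is.list(R)) R <- matrix(unlist(R), nrow = length(f$coefs))
  piv <- attr(R, "pivot") %||% seq_along(f$coefs)
  V <- R %*% f$Vb[piv, piv, drop = FALSE] %*% t(R)
  V <- (V + t(V)) / 2
  p <- drop(R %*% f$coefs[piv])
  eg <- eigen(V, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  k <- min(sum(pos), max(1L, as.integer(round(f$edf))))
  u <- drop(crossprod(eg$vectors[, seq_len(k), drop = FALSE], p))
  stat <- sum(u^2 / eg$values[seq_len(k)])
  if (fit$family == "gaussian") {
    # curves vary between patients, so the effective replication for a
    # functional term is the number of patients: an F reference with
    # patient-level denominator df keeps the test calibrated at cohort
    # sizes like 70, where the chi-square is anti-conservative
    df2 <- max(fit$n_patients - k - 1, 1)
    stats::pf(stat / k, k, df2, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = k, lower.tail = FALSE)
  }
}

# Run expr with a temporary RNG state seeded by `seed`. The seed is
# forced before the caller's RNG state is captured, so that an RNG-using
# seed expression is not rewound by the restore.
with_seed <- function(seed, expr) {
  force(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Resample whole patients with replacement, preserving each patient's
# sessions and curves; duplicated patients get fresh subject ids.
resample_cohort <- function(data) {
  n <- nrow(data$patients)
  idx <- sample.int(n, n, replace = TRUE)
  pt <- data$patients[idx, , drop = FALSE]
  old_ids <- pt$subject_id
  pt$subject_id <- sprintf("bs%03d", seq_len(n))
  curves <- lapply(data$curves, function(M) {
    M2 <- M[idx, , drop = FALSE]; rownames(M2) <- pt$subject_id; M2
  })
  sbp_split <- split(data$sbp, data$sbp$subject_id)
  sbp <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- sbp_split[[old_ids[i]]]
    if (is.null(s)) return(NULL)
    s$subject_id <- pt$subject_id[i]
    s
  }))
  rownames(sbp) <- NULL
  cohort_data(pt, curves, sbp)
}

#' Cluster-bootstrap percentile band for a functional coefficient
#'
#' Resamples patients with replacement (keeping each patient's sessions
#' and curves together, so within-patient correlation is respected),
#' refits the model on every replicate, and forms the pointwise
#' percentile band of the replicate coefficient functions. Deterministic
#' given `seed`.
#'
#' @param data A [cohort_data()].
#' @param spec A [basis_spec()].
#' @param term Functional term name.
#' @param B Number of bootstrap replicates (>= 50), default 200.
#' @param seed Integer RNG seed.
#' @param level Coverage level, default 0.95.
#' @param family `"gaussian"` (SBP model) or `"binomial"` (mortality).
#' @param options Passed to the fitter ([sofr_options()] for Gaussian).
#' @return A `confidence_band` (method `"bootstrap"`) whose `estimate` is
#'   the full-data fit.
#' @export
bootstrap_band <- function(data, spec = basis_spec(), term, B = 200L,
                           seed = 1L, level = 0.95, family = "gaussian",
                           options = NULL) {
  if (B < 50L) stop("need B >= 50 bootstrap replicates", call. = FALSE)
  family <- match.arg(family, c("gaussian", "binomial"))
  fit_one <- function(d) {
    if (family == "gaussian")
      fit_sofr_gaussian(d, spec, options %||% sofr_options())
    else
      fit_sofr_binomial(d, spec)
  }
  full <- fit_one(data)
  f <- get_functional(full, term)
  betas <- with_seed(seed, {
    res <- matrix(NA_real_, B, length(f$grid))
    fails <- 0L
    for (b in seq_len(B)) {
      rep_fit <- tryCatch(fit_one(resample_cohort(data)),
                          error = function(e) NULL)
      if (is.null(rep_fit)) fails <- fails + 1L
      else res[b, ] <- rep_fit$functional[[term]]$beta
    }
    if (fails > 0.2 * B)
      stop(sprintf("bootstrap failure: %d of %d replicates did not fit",
                   fails, B), call. = FALSE)
    res[stats::complete.cases(res), , drop = FALSE]
  })
  a <- (1 - level) / 2
  structure(list(
    t = f$grid, estimate = f$beta,
    lower = apply(betas, 2, stats::quantile, probs = a),
    upper = apply(betas, 2, stats::quantile, probs = 1 - a),
    level = level, method = "bootstrap", term = term,
    n_replicates = nrow(betas)),
    class = "confidence_band")
}
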