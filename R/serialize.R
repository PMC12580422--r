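# JSON serialization of fit results.

#' Serialize a fit to JSON
#'
#' Writes a nested JSON document: family, scalar coefficient table,
#' per-term functional coefficients (grid, estimate, pointwise SE, basis
#' coefficients, their covariance, smoothing parameter, effective df,
#' centering curve), variance components and fit statistics. The file can
#' be restored with [read_fit_json()] for downstream inference
#' ([pointwise_band()], [global_pvalue()], [perturbation_effect()]).
#'
#' @param fit A `sofr_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sofr_fit"))
  doc <- list(
    family = fit$family,
    basis = list(n_basis = fit$spec$n_basis, order = fit$spec$order,
                 penalty_order = fit$spec$penalty_order),
    scalar_terms = fit$scalar,
    functional_terms = lapply(unname(fit$functional), function(f)
      list(term = f$term,
           lambda = if (is.finite(f$lambda)) f$lambda else NULL,
           edf = f$edf, units = f$units,
           grid = f$grid, beta = f$beta, se = f$se, coefs = f$coefs,
           Vb = f$Vb, center = f$center,
           design_R = if (!is.null(f$design_R)) unclass(f$design_R),
           design_pivot = attr(f$design_R, "pivot"))),
    variance_components = list(sigma_b = fit$sigma_b,
                               sigma_eps = fit$sigma_eps),
    fit_stats = list(loglik = fit$loglik, aic = fit$aic,
                     deviance = fit$deviance, edf_total = fit$edf_total,
                     variance_explained = fit$variance_explained,
                     n_obs = fit$n_obs, n_patients = fit$n_patients))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Restore a fit from JSON
#'
#' Rebuilds a lightweight `sofr_fit` from a [write_fit_json()] file,
#' sufficient for bands, global tests and perturbation effects (not for
#' refitting).
#'
#' @param path JSON path.
#' @return A `sofr_fit` object.
#' @export
read_fit_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  functional <- list()
  ft <- doc$functional_terms
  if (length(ft)) {
    if (is.data.frame(ft)) ft <- split(ft, seq_len(nrow(ft)))
    for (f in ft) {
      f <- as.list(f)
      for (v in c("grid", "beta", "se", "coefs", "center"))
        if (!is.null(f[[v]])) f[[v]] <- as.numeric(unlist(f[[v]]))
      f$lambda <- if (is.null(f$lambda) || is.na(f$lambda)) Inf
                  else as.numeric(f$lambda)
      f$edf <- as.numeric(f$edf)
      K <- length(f$coefs)
      # JSON lists of rows come back row-major; already-simplified
      # matrices are used as is
      as_mat <- function(m) {
        if (is.matrix(m)) return(m)
        matrix(as.numeric(unlist(m)), K, K, byrow = TRUE)
      }
      f$Vb <- as_mat(f$Vb)
      if (!is.null(f$design_R)) {
        R <- as_mat(f$design_R)
        attr(R, "pivot") <- as.integer(unlist(f$design_pivot))
        f$design_R <- R
        f$design_pivot <- NULL
      }
      functional[[f$term]] <- f
    }
  }
  structure(list(
    family = doc$family,
    scalar = as.data.frame(doc$scalar_terms),
    functional = functional,
    sigma_b = doc$variance_components$sigma_b,
    sigma_eps = doc$variance_components$sigma_eps,
    variance_explained = doc$fit_stats$variance_explained,
    loglik = doc$fit_stats$loglik, aic = doc$fit_stats$aic,
    deviance = doc$fit_stats$deviance,
    edf_total = doc$fit_stats$edf_total,
    n_obs = doc$fit_stats$n_obs, n_patients = doc$fit_stats$n_patients,
    spec = basis_spec(doc$basis$n_basis, doc$basis$order,
                      doc$basis$penalty_order)),
    class = "sofr_fit")
}
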