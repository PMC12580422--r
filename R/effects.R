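# Interpretable effect measures for fitted functional coefficients.

#' Define a curve perturbation
#'
#' A constant additive shift of `delta` curve-units applied over the
#' cycle window `[t_start, t_end]` — e.g. `delta = -5` for GLS that is
#' 5 percentage points more negative during diastole, or `delta = +5`
#' for torsion 5 degrees higher, relative to a reference curve.
#'
#' @param term Functional term name.
#' @param delta Shift in curve units (percent for strain, degrees for
#'   torsion).
#' @param t_start,t_end Window on the cycle-proportion axis; defaults
#'   `[0.5, 1]`, the diastolic half of the cycle. Require
#'   `0 <= t_start < t_end <= 1`.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(term, delta, t_start = 0.5, t_end = 1.0) {
  if (!(t_start >= 0 && t_start < t_end && t_end <= 1))
    stop("need 0 <= t_start < t_end <= 1", call. = FALSE)
  structure(list(term = term, delta = delta,
                 t_start = t_start, t_end = t_end),
            class = "perturbation")
}

#' Effect of a curve perturbation on the fitted outcome
#'
#' Computes the change in linear predictor
#' \eqn{\eta = \delta \int_{t_0}^{t_1} \beta(t)\,dt} by trapezoid
#' quadrature with the window endpoints snapped to the nearest grid
#' points (integrals stay exact for the piecewise-linear representation).
#' For a binomial fit the result is the odds ratio \eqn{e^\eta} with a
#' delta-method Wald CI on the log scale; for a Gaussian fit it is the
#' expected SBP change in mmHg.
#'
#' @param fit A `sofr_fit`.
#' @param pert A [perturbation()].
#' @param level CI level, default 0.95.
#' @return An object of class `perturbation_effect` with `estimate`,
#'   `ci_low`, `ci_high`, `scale` (`"or"` or `"mmHg"`), `se_log` /
#'   `se`, and the snapped window.
#' @export
perturbation_effect <- function(fit, pert, level = 0.95) {
  stopifnot(inherits(pert, "perturbation"))
  f <- get_functional(fit, pert$term)
  L <- length(f$grid)
  h <- 1 / (L - 1)
  i0 <- round(pert$t_start / h) + 1L
  i1 <- round(pert$t_end / h) + 1L
  if (i1 <= i0)
    stop("perturbation window collapses after grid snapping", call. = FALSE)
  w <- rep(h, i1 - i0 + 1L)
  w[c(1L, length(w))] <- h / 2
  # eta = delta * sum_l w_l beta(t_l) over the window
  eta <- pert$delta * sum(w * f$beta[i0:i1])
  # propagate through the basis: c' theta with c = delta * w' B[window, ]
  Bw <- basis_rows_for(fit, f)[i0:i1, , drop = FALSE]
  cf <- pert$delta * drop(w %*% Bw)
  se <- sqrt(max(drop(cf %*% f$Vb %*% cf), 0))
  z <- stats::qnorm((1 + level) / 2)
  if (fit$family == "binomial") {
    structure(list(term = pert$term, delta = pert$delta,
                   window = c((i0 - 1) * h, (i1 - 1) * h),
                   estimate = exp(eta), ci_low = exp(eta - z * se),
                   ci_high = exp(eta + z * se), scale = "or",
                   log_estimate = eta, se_log = se, level = level),
              class = "perturbation_effect")
  } else {
    structure(list(term = pert$term, delta = pert$delta,
                   window = c((i0 - 1) * h, (i1 - 1) * h),
                   estimate = eta, ci_low = eta - z * se,
                   ci_high = eta + z * se, scale = "mmHg",
                   se = se, level = level),
              class = "perturbation_effect")
  }
}

# Basis matrix rows for a functional term; rebuilt from the fit's spec so
# that deserialized fits work too.
basis_rows_for <- function(fit, f) {
  build_basis(fit$spec, L = length(f$grid))$B
}

#' @export
print.perturbation_effect <- function(x, ...) {
  unit <- if (x$scale == "or") "odds ratio" else "mmHg change"
  cat(sprintf(
    "<perturbation_effect> %s %+g units over t in [%.3f, %.3f]: %s %.3f (%.0f%% CI %.3f-%.3f)\n",
    x$term, x$delta, x$window[1], x$window[2], unit, x$estimate,
    100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

effects_to_frame <- function(effects) {
  do.call(rbind, lapply(effects, function(e) {
    data.frame(term = e$term, delta = e$delta,
               t_start = e$window[1], t_end = e$window[2],
               scale = e$scale, estimate = e$estimate,
               ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)
  }))
}

# Open a graphics file; falls back to pdf when no bitmap device exists.
save_plot <- function(p, path, width = 6, height = 4) {
  ok <- tryCatch({
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    path <- sub("\\.png$", ".pdf", path)
    ggplot2::ggsave(path, p, width = width, height = height)
  }
  path
}

band_frame <- function(fit, term, level = 0.95) {
  bd <- pointwise_band(fit, term, level)
  f <- get_functional(fit, term)
  data.frame(t = bd$t, beta = bd$estimate, se = f$se,
             lower = bd$lower, upper = bd$upper)
}

#' Write coefficient tables, band plots and mean-curve plots
#'
#' For each fit: a flat coefficients CSV (scalar covariates with 95% CIs
#' and p-values), and per functional term a data CSV (`t`, `beta`, `se`,
#' `lower`, `upper`) plus a plot of \eqn{\hat\beta(t)} with its pointwise
#' band and a dashed zero line against cycle proportion. Mean (centering)
#' curves are written alongside. Perturbation effects, when given, go to
#' `effects.csv`.
#'
#' @param fits A named list of `sofr_fit` objects (names label output
#'   files) or a single fit.
#' @param effects Optional list of [perturbation_effect()] results.
#' @param out_path Output directory, created if needed.
#' @param level Band level, default 0.95.
#' @return Character vector of the files written.
#' @export
render_report <- function(fits, effects = list(), out_path,
                          level = 0.95) {
  if (inherits(fits, "sofr_fit")) fits <- list(fit = fits)
  if (!length(fits)) stop("need at least one fit", call. = FALSE)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("fit", seq_along(fits))
  ok <- tryCatch({
    dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
    file.access(out_path, 2) == 0
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to output path: ", out_path, call. = FALSE)

  files <- character(0)
  emit <- function(p) files <<- c(files, p)

  for (nm in names(fits)) {
    fit <- fits[[nm]]
    cov <- fit$scalar[fit$scalar$group == "covariate", , drop = FALSE]
    if (!nrow(cov)) cov <- fit$scalar
    tab <- data.frame(term = cov$term, coefficient = cov$estimate,
                      ci_low = cov$ci_low, ci_high = cov$ci_high,
                      p = cov$p, stringsAsFactors = FALSE)
    p_coef <- file.path(out_path, paste0(nm, "_coefficients.csv"))
    utils::write.csv(tab, p_coef, row.names = FALSE)
    emit(p_coef)

    for (term in names(fit$functional)) {
      df <- band_frame(fit, term, level)
      p_csv <- file.path(out_path, paste0(nm, "_beta_", term, ".csv"))
      utils::write.csv(df, p_csv, row.names = FALSE)
      emit(p_csv)
      ylab <- if (fit$family == "binomial") "log(OR)" else "mmHg per unit"
      p <- ggplot2::ggplot(df, ggplot2::aes(x = t, y = beta)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                             fill = "grey80") +
        ggplot2::geom_line(linewidth = 0.8) +
        ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
        ggplot2::labs(x = "cardiac-cycle proportion",
                      y = ylab,
                      title = sprintf("%s effect (%s model)", term,
                                      fit$family)) +
        ggplot2::theme_minimal()
      emit(save_plot(p, file.path(out_path,
                                  paste0(nm, "_beta_", term, ".png"))))
    }

    ctr <- lapply(fit$functional, function(f) f$center)
    ctr <- Filter(Negate(is.null), ctr)
    if (length(ctr)) {
      mdf <- do.call(rbind, lapply(names(ctr), function(term)
        data.frame(term = term, t = cycle_grid(length(ctr[[term]])),
                   mean_value = ctr[[term]])))
      p_csv <- file.path(out_path, paste0(nm, "_mean_curves.csv"))
      utils::write.csv(mdf, p_csv, row.names = FALSE)
      emit(p_csv)
      p <- ggplot2::ggplot(mdf, ggplot2::aes(x = t, y = mean_value)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~term, scales = "free_y") +
        ggplot2::labs(x = "cardiac-cycle proportion", y = "mean curve") +
        ggplot2::theme_minimal()
      emit(save_plot(p, file.path(out_path,
                                  paste0(nm, "_mean_curves.png"))))
    }
  }

  if (length(effects)) {
    p_eff <- file.path(out_path, "effects.csv")
    utils::write.csv(effects_to_frame(effects), p_eff, row.names = FALSE)
    emit(p_eff)
  }
  files
}
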