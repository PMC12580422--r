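# End-to-end pipeline glue.

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()], simulated input)
#' or `input_dir` (directory with `patients.csv`, `sbp.csv`,
#' `curves.csv`) must be given.
#'
#' @param synthetic Optional [synthetic_config()].
#' @param input_dir Optional directory of real input CSVs.
#' @param spec A [basis_spec()].
#' @param bootstrap_B Bootstrap replicates for the torsion SBP band;
#'   0 disables the bootstrap stage. Default 0 (the Wald bands are
#'   always produced; the cluster bootstrap is opt-in because of its
#'   cost).
#' @param seed Integer seed used for simulation and bootstrap.
#' @param out_dir Output directory.
#' @param verbose Log each stage to stderr (default `TRUE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL,
                            spec = basis_spec(), bootstrap_B = 0L,
                            seed = 1L, out_dir, verbose = TRUE) {
  if (is.null(synthetic) == is.null(input_dir))
    stop("give exactly one of `synthetic` or `input_dir`", call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 spec = spec, bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: acquire data (simulate, or read and validate), fit the
#' Gaussian SBP model, fit the binomial mortality model, compute the
#' standard diastolic perturbation effects (GLS −5 units and torsion
#' +5 units after t = 0.5 on the mortality odds), optionally a cluster
#' bootstrap band, and render report files. A manifest JSON listing
#' every output (MD5 checksums for text artifacts; image files are
#' listed by size, since graphics devices embed metadata) is written
#' last; on stage failure the manifest of completed stages is still
#' written before the error propagates.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (class `pipeline_manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (config$verbose)
    message(sprintf("[untwistr %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  stages <- character(0)
  files <- character(0)
  finish_manifest <- function() {
    manifest <- list(
      seed = config$seed,
      n_basis = config$spec$n_basis,
      bootstrap_B = config$bootstrap_B,
      stages_completed = stages,
      files = lapply(files, function(p) {
        rec <- list(path = basename(p), bytes = file.size(p))
        if (grepl("\\.(csv|json)$", p)) rec$md5 <- unname(tools::md5sum(p))
        rec
      }))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    structure(manifest, class = "pipeline_manifest")
  }
  run_stage <- function(name, expr) {
    log_msg("stage %s (seed %d)", name, config$seed)
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      finish_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages <<- c(stages, name)
    log_msg("stage %s done (%.1f s)", name, proc.time()[3] - t0)
    res
  }

  cohort <- if (!is.null(config$synthetic)) {
    run_stage("simulate", {
      ch <- generate_cohort(config$synthetic, config$seed)
      files <<- c(files, write_cohort(ch, file.path(out, "data")))
      ch
    })
  } else {
    run_stage("load", {
      viol <- validate_inputs(config$input_dir)
      if (nrow(viol))
        stop(sprintf("input validation failed (%d violations, first: %s)",
                     nrow(viol), viol$detail[1]))
      read_cohort(config$input_dir)
    })
  }

  fit_sbp <- run_stage("fit-sbp", {
    ft <- fit_sofr_gaussian(cohort, config$spec)
    p <- file.path(out, "fit_sbp.json")
    write_fit_json(ft, p)
    files <<- c(files, p)
    ft
  })

  fit_mort <- run_stage("fit-mortality", {
    ft <- fit_sofr_binomial(cohort, config$spec)
    p <- file.path(out, "fit_mortality.json")
    write_fit_json(ft, p)
    files <<- c(files, p)
    ft
  })

  effects <- run_stage("effects", {
    eff <- list(
      perturbation_effect(fit_mort, perturbation("gls", -5)),
      perturbation_effect(fit_mort, perturbation("torsion", +5)),
      perturbation_effect(fit_sbp, perturbation("torsion", +5)))
    p <- file.path(out, "effects.json")
    jsonlite::write_json(effects_to_frame(eff), p, auto_unbox = TRUE,
                         digits = NA)
    files <<- c(files, p)
    eff
  })

  if (config$bootstrap_B >= 50L) {
    run_stage("bootstrap", {
      bb <- bootstrap_band(cohort, config$spec, "torsion",
                           B = config$bootstrap_B, seed = config$seed)
      p <- file.path(out, "bootstrap_band_torsion.csv")
      utils::write.csv(data.frame(t = bb$t, estimate = bb$estimate,
                                  lower = bb$lower, upper = bb$upper),
                       p, row.names = FALSE)
      files <<- c(files, p)
      bb
    })
  }

  run_stage("report", {
    files <<- c(files, render_report(
      list(sbp = fit_sbp, mortality = fit_mort), effects,
      file.path(out, "report")))
  })

  manifest <- finish_manifest()
  log_msg("pipeline complete: %d files", length(files))
  invisible(manifest)
}
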