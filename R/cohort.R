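SCALAR_COVARIATES <- c("age", "sex", "hypertension", "diabetes",
                       "dialysis_vintage", "ultrafiltrate", "ivc_diameter",
                       "lv_mass_indexed")

FUNCTIONAL_TERMS <- c("torsion", "gls", "rv_free_wall")

#' Assemble a cohort dataset
#'
#' The regression input: one row per patient with scalar covariates and a
#' death indicator, normalized curves for the three functional predictors,
#' and the repeated systolic blood pressure (SBP) measurements
#' (3 sessions x 7 occasions per patient; missing entries allowed and
#' dropped row-wise at fit time).
#'
#' @param patients Data frame with columns `subject_id`, the scalar
#'   covariates `age` (years), `sex` (0/1), `hypertension` (0/1),
#'   `diabetes` (0/1), `dialysis_vintage` (years), `ultrafiltrate` (mL),
#'   `ivc_diameter` (mm), `lv_mass_indexed` (g/m2), and `death` (0/1).
#' @param curves Named list (`torsion`, `gls`, `rv_free_wall`) of n x 33
#'   matrices, rows aligned with `patients$subject_id`.
#' @param sbp Long data frame with columns `subject_id`, `session` (1-3),
#'   `occasion` (1-7), `sbp` (mmHg, each present value in (30, 300)).
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(patients, curves, sbp) {
  need <- c("subject_id", SCALAR_COVARIATES, "death")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    stop("patients table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  patients$subject_id <- as.character(patients$subject_id)
  if (anyDuplicated(patients$subject_id))
    stop("duplicate subject_id in patients table", call. = FALSE)
  for (v in SCALAR_COVARIATES)
    if (!all(is.finite(patients[[v]])))
      stop("non-finite values in covariate ", v, call. = FALSE)
  if (!all(patients$death %in% c(0, 1)))
    stop("death must be 0/1", call. = FALSE)
  if (!is.list(curves) || !all(FUNCTIONAL_TERMS %in% names(curves)))
    stop("curves must be a named list with torsion, gls, rv_free_wall",
         call. = FALSE)
  n <- nrow(patients)
  for (term in FUNCTIONAL_TERMS) {
    M <- curves[[term]]
    if (!is.matrix(M) || nrow(M) != n || ncol(M) != 33L)
      stop(sprintf("curves$%s must be a %d x 33 matrix", term, n),
           call. = FALSE)
    if (!all(is.finite(M)))
      stop("non-finite values in curves$", term, call. = FALSE)
    rownames(curves[[term]]) <- patients$subject_id
  }
  needs <- c("subject_id", "session", "occasion", "sbp")
  if (!all(needs %in% names(sbp)))
    stop("sbp table must have columns subject_id, session, occasion, sbp",
         call. = FALSE)
  sbp$subject_id <- as.character(sbp$subject_id)
  ok <- is.na(sbp$sbp) | (sbp$sbp > 30 & sbp$sbp < 300)
  if (!all(ok))
    stop("SBP values must lie in (30, 300) mmHg", call. = FALSE)
  if (!all(sbp$subject_id %in% patients$subject_id))
    stop("sbp table contains unknown subject_id", call. = FALSE)
  structure(list(patients = patients, curves = curves, sbp = sbp),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf(
    "<cohort_data> %d patients, %d SBP rows, %d deaths (%.1f%%)\n",
    nrow(x$patients), sum(!is.na(x$sbp$sbp)), sum(x$patients$death),
    100 * mean(x$patients$death)))
  invisible(x)
}

#' Write a cohort dataset as three CSV files
#'
#' Writes `patients.csv` (one row per patient), `sbp.csv` (long format)
#' and `curves.csv` (long format, see [write_curves()]) under `dir`.
#'
#' @param data A [cohort_data()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(data, dir) {
  stopifnot(inherits(data, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             sbp = file.path(dir, "sbp.csv"),
             curves = file.path(dir, "curves.csv"))
  utils::write.csv(data$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(data$sbp, paths["sbp"], row.names = FALSE)
  curves <- unlist(lapply(FUNCTIONAL_TERMS, function(term) {
    M <- data$curves[[term]]
    lapply(seq_len(nrow(M)), function(i)
      normalized_curve(M[i, ], term, data$patients$subject_id[i]))
  }), recursive = FALSE)
  write_curves(curves, paths["curves"])
  invisible(paths)
}

#' Read a cohort dataset from CSV files
#'
#' Inverse of [write_cohort()].
#'
#' @param dir Directory holding `patients.csv`, `sbp.csv`, `curves.csv`,
#'   or a named character vector of the three paths.
#' @return A [cohort_data()] object.
#' @export
read_cohort <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 3L && !is.null(names(dir)))
    dir
  else c(patients = file.path(dir, "patients.csv"),
         sbp = file.path(dir, "sbp.csv"),
         curves = file.path(dir, "curves.csv"))
  for (p in paths) if (!file.exists(p))
    stop("missing input file: ", p, call. = FALSE)
  patients <- utils::read.csv(paths["patients"], stringsAsFactors = FALSE)
  patients$subject_id <- as.character(patients$subject_id)
  sbp <- utils::read.csv(paths["sbp"], stringsAsFactors = FALSE)
  curve_list <- read_curves(paths["curves"])
  curves <- lapply(FUNCTIONAL_TERMS, function(term) {
    sel <- Filter(function(cv) cv$modality == term, curve_list)
    ids <- vapply(sel, function(cv) cv$subject_id, character(1))
    M <- curves_to_matrix(sel)
    rownames(M) <- ids
    M[match(patients$subject_id, ids), , drop = FALSE]
  })
  names(curves) <- FUNCTIONAL_TERMS
  cohort_data(patients, curves, sbp)
}

#' Validate cohort input files
#'
#' Checks schema, value ranges (SBP in (30, 300) mmHg, 0/1 indicators,
#' 33-sample curves) and referential integrity (every SBP subject has a
#' complete curve set). Returns a machine-readable violation table rather
#' than stopping at the first problem.
#'
#' @param paths Directory or named vector as in [read_cohort()].
#' @return Data frame with columns `check`, `subject_id`, `detail`; zero
#'   rows when the inputs are clean.
#' @export
validate_inputs <- function(paths) {
  if (is.character(paths) && length(paths) == 1L)
    paths <- c(patients = file.path(paths, "patients.csv"),
               sbp = file.path(paths, "sbp.csv"),
               curves = file.path(paths, "curves.csv"))
  for (p in paths) if (!file.exists(p))
    stop("unreadable input file: ", p, call. = FALSE)
  viol <- list()
  add <- function(check, subject_id, detail)
    viol[[length(viol) + 1L]] <<- data.frame(
      check = check, subject_id = as.character(subject_id), detail = detail,
      stringsAsFactors = FALSE)

  patients <- utils::read.csv(paths["patients"], stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", SCALAR_COVARIATES, "death"),
                  names(patients))
  if (length(miss))
    add("schema", NA, paste("patients.csv missing columns:",
                            paste(miss, collapse = ", ")))
  sbp <- utils::read.csv(paths["sbp"], stringsAsFactors = FALSE)
  if (!all(c("subject_id", "session", "occasion", "sbp") %in% names(sbp)))
    add("schema", NA, "sbp.csv missing required columns")
  curves <- utils::read.csv(paths["curves"], stringsAsFactors = FALSE)
  if (!all(c("subject_id", "modality", "t", "value") %in% names(curves)))
    add("schema", NA, "curves.csv missing required columns")
  if (length(viol)) return(do.call(rbind, viol))

  bad <- which(!is.na(sbp$sbp) & (sbp$sbp <= 30 | sbp$sbp >= 300))
  for (i in bad)
    add("sbp_range", sbp$subject_id[i],
        sprintf("session %s occasion %s: SBP %.1f outside (30, 300)",
                sbp$session[i], sbp$occasion[i], sbp$sbp[i]))
  for (v in c("sex", "hypertension", "diabetes", "death")) {
    bad <- which(!patients[[v]] %in% c(0, 1))
    for (i in bad)
      add("indicator_range", patients$subject_id[i],
          sprintf("%s = %s is not 0/1", v, patients[[v]][i]))
  }
  cnt <- table(curves$subject_id, curves$modality)
  for (id in rownames(cnt))
    for (m in colnames(cnt))
      if (cnt[id, m] != 0L && cnt[id, m] != 33L)
        add("curve_length", id,
            sprintf("%s curve has %d samples, expected 33", m, cnt[id, m]))
  for (id in unique(sbp$subject_id)) {
    have <- if (id %in% rownames(cnt))
      colnames(cnt)[cnt[id, ] > 0] else character(0)
    lost <- setdiff(FUNCTIONAL_TERMS, have)
    if (length(lost))
      add("integrity", id,
          paste("SBP present but no curves for:",
                paste(lost, collapse = ", ")))
  }
  if (!length(viol))
    return(data.frame(check = character(0), subject_id = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, viol)
}
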