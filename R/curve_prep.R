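#' @keywords internal
"_PACKAGE"

MODALITIES <- c("gls", "rotation_apical", "rotation_basal", "rv_free_wall",
                "torsion")

# modalities whose physiological peak is the most negative value
NEGATIVE_PEAK_MODALITIES <- c("gls", "rv_free_wall")

#' Uniform cardiac-cycle grid
#'
#' Grid points \eqn{t_l = (l-1)/(L-1)} on \eqn{[0, 1]}, the cardiac-cycle
#' proportion at which every normalized curve is sampled. The default
#' `L = 33` matches the fixed trace length used throughout the package.
#'
#' @param L Number of grid points (>= 2).
#' @return Numeric vector of length `L`, strictly increasing from 0 to 1.
#' @export
cycle_grid <- function(L = 33L) {
  if (length(L) != 1L || !is.finite(L) || L < 2)
    stop("`L` must be a single integer >= 2", call. = FALSE)
  L <- as.integer(L)
  (seq_len(L) - 1) / (L - 1)
}

#' Construct a raw strain/rotation trace
#'
#' A trace is the numerical series exported for one cardiac cycle of one
#' subject: longitudinal strain (percent), rotation (degrees), right
#' ventricular free-wall strain (percent) or an already-formed torsion
#' curve. Traces may have arbitrary length; they are put on the common
#' cycle grid by [resample_trace()].
#'
#' @param values Numeric vector, length >= 2, all finite. Strain in percent
#'   or rotation in degrees.
#' @param modality One of `"gls"`, `"rotation_apical"`, `"rotation_basal"`,
#'   `"rv_free_wall"`, `"torsion"`.
#' @param subject_id Opaque subject identifier (coerced to character).
#' @return An object of class `strain_trace`.
#' @export
strain_trace <- function(values, modality, subject_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a strain trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("strain trace contains non-finite values", call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  structure(
    list(values = values, modality = modality,
         subject_id = as.character(subject_id)),
    class = "strain_trace"
  )
}

#' Construct a normalized curve on the fixed cycle grid
#'
#' @param values Numeric vector of length `L` (default 33), all finite.
#' @param modality Modality tag, see [strain_trace()].
#' @param subject_id Subject identifier.
#' @param L Grid length; the package standard is 33.
#' @return An object of class `normalized_curve` with fields `values`,
#'   `grid`, `modality`, `subject_id`.
#' @export
normalized_curve <- function(values, modality, subject_id = NA_character_,
                             L = 33L) {
  values <- as.numeric(values)
  if (length(values) != L)
    stop(sprintf("normalized curve must have exactly %d samples, got %d",
                 L, length(values)), call. = FALSE)
  if (!all(is.finite(values)))
    stop("normalized curve contains non-finite values", call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  structure(
    list(values = values, grid = cycle_grid(L), modality = modality,
         subject_id = as.character(subject_id)),
    class = "normalized_curve"
  )
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve> %s, subject %s, %d samples on [0,1]\n",
              x$modality, x$subject_id, length(x$values)))
  invisible(x)
}

#' Time-normalize a trace to the fixed cardiac-cycle grid
#'
#' Places the input samples at equally spaced positions spanning
#' \eqn{[0, 1]} and linearly interpolates onto the `L`-point cycle grid.
#' This removes heart-rate and frame-rate variation so that curves from
#' different subjects are comparable point-by-point. Endpoints of the
#' input are preserved exactly, and linear interpolation cannot overshoot
#' the input range.
#'
#' @param trace A [strain_trace()] (or bare numeric vector, in which case
#'   `modality`/`subject_id` must be supplied via `...` through
#'   [strain_trace()] first).
#' @param L Target grid length, default 33.
#' @return A [normalized_curve()] of length `L`.
#' @export
resample_trace <- function(trace, L = 33L) {
  if (!inherits(trace, "strain_trace"))
    stop("`trace` must be a strain_trace object", call. = FALSE)
  n <- length(trace$values)
  x_in <- (seq_len(n) - 1) / (n - 1)
  out <- stats::approx(x = x_in, y = trace$values, xout = cycle_grid(L),
                       method = "linear", ties = "ordered")$y
  # guard against floating-point drift at the endpoints
  out[1] <- trace$values[1]
  out[L] <- trace$values[n]
  normalized_curve(out, trace$modality, trace$subject_id, L = L)
}

#' Left-ventricular torsion from apical and basal rotation
#'
#' Torsion (twist) is the pointwise difference between apical and basal
#' rotation across the cardiac cycle; its decline after the systolic peak
#' is the diastolic untwist.
#'
#' @param apical,basal Normalized curves with modalities
#'   `"rotation_apical"` and `"rotation_basal"`, both on the same grid.
#' @return A [normalized_curve()] with modality `"torsion"`.
#' @export
compute_torsion <- function(apical, basal) {
  if (!inherits(apical, "normalized_curve") ||
      !inherits(basal, "normalized_curve"))
    stop("inputs must be normalized_curve objects", call. = FALSE)
  if (apical$modality != "rotation_apical" ||
      basal$modality != "rotation_basal")
    stop("modalities must be rotation_apical and rotation_basal",
         call. = FALSE)
  if (length(apical$values) != length(basal$values))
    stop("apical and basal curves have different lengths", call. = FALSE)
  normalized_curve(apical$values - basal$values, "torsion",
                   apical$subject_id, L = length(apical$values))
}

#' Peak value and its timing for a normalized curve
#'
#' For shortening modalities (`gls`, `rv_free_wall`) the peak is the most
#' negative sample; for torsion and rotations it is the maximum. Ties are
#' broken by the earliest time.
#'
#' @param curve A [normalized_curve()].
#' @return A list with `peak_value` (signed, curve units) and
#'   `time_to_peak` (cycle proportion, on the grid).
#' @export
summarize_curve <- function(curve) {
  if (!inherits(curve, "normalized_curve"))
    stop("`curve` must be a normalized_curve", call. = FALSE)
  idx <- if (curve$modality %in% NEGATIVE_PEAK_MODALITIES)
    which.min(curve$values) else which.max(curve$values)
  list(peak_value = curve$values[idx], time_to_peak = curve$grid[idx])
}

#' Read exported traces from delimited text
#'
#' Accepts either a long-format file with columns `subject_id`,
#' `modality`, `frame_index`, `value` (frame indices contiguous from 0 or
#' 1 within each trace) or a single-trace file with one `value` column.
#' The delimiter is autodetected from the extension: `.csv` is
#' comma-separated, `.tsv`/`.txt` tab-separated.
#'
#' @param path File path.
#' @param modality,subject_id Required when the file holds a single bare
#'   trace; ignored for long format.
#' @return A list of [strain_trace()] objects.
#' @export
read_traces <- function(path, modality = NULL, subject_id = NULL) {
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  long_cols <- c("subject_id", "modality", "frame_index", "value")
  if (all(long_cols %in% names(df))) {
    keys <- unique(df[, c("subject_id", "modality")])
    traces <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- df[df$subject_id == keys$subject_id[i] &
                  df$modality == keys$modality[i], ]
      sub <- sub[order(sub$frame_index), ]
      fi <- sub$frame_index
      if (!all(diff(fi) == 1) || !(fi[1] %in% c(0L, 1L)))
        stop(sprintf(
          "frame_index for subject %s / %s must be contiguous from 0 or 1",
          keys$subject_id[i], keys$modality[i]), call. = FALSE)
      strain_trace(sub$value, keys$modality[i], keys$subject_id[i])
    })
    return(traces)
  }
  if ("value" %in% names(df)) {
    if (is.null(modality))
      stop("single-trace file needs `modality`", call. = FALSE)
    return(list(strain_trace(df$value, modality,
                             subject_id %||% NA_character_)))
  }
  stop("unrecognized trace file layout: need long-format columns ",
       "subject_id/modality/frame_index/value or a `value` column",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write normalized curves as long-format CSV
#'
#' Columns: `subject_id`, `modality`, `t`, `value`, with `t` printed at
#' 8 decimals so that the grid round-trips exactly.
#'
#' @param curves A list of [normalized_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (!length(curves)) stop("no curves to write", call. = FALSE)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(subject_id = cv$subject_id, modality = cv$modality,
               t = sprintf("%.8f", cv$grid),
               value = cv$values, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read normalized curves from long-format CSV
#'
#' Inverse of [write_curves()].
#'
#' @param path CSV path with columns `subject_id`, `modality`, `t`, `value`.
#' @return A list of [normalized_curve()] objects.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "modality", "t", "value")
  if (!all(need %in% names(df)))
    stop("curves file must have columns subject_id, modality, t, value",
         call. = FALSE)
  keys <- unique(df[, c("subject_id", "modality")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$subject_id == keys$subject_id[i] &
                df$modality == keys$modality[i], ]
    sub <- sub[order(sub$t), ]
    normalized_curve(sub$value, keys$modality[i], keys$subject_id[i],
                     L = nrow(sub))
  })
}
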