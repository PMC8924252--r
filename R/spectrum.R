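# In-memory containers for centroided spectra and acquisition runs.

#' Construct a centroided spectrum
#'
#' @param ms_level 1 (survey) or 2 (fragment).
#' @param rt Retention time in seconds.
#' @param mz Numeric vector of m/z values (Th), strictly increasing.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param precursor_mz,precursor_intensity Selected precursor (DDA MS2).
#' @param isolation_lower,isolation_upper Isolation window bounds (DIA MS2),
#'   half-open `[lower, upper)`.
#' @param collision_energy Optional collision-energy range label (e.g.
#'   `"20-50"`).
#' @return Object of class `spectrum`.
#' @export
new_spectrum <- function(ms_level, rt, mz, intensity,
                         precursor_mz = NA_real_, precursor_intensity = NA_real_,
                         isolation_lower = NA_real_, isolation_upper = NA_real_,
                         collision_energy = NA_character_) {
  stopifnot(ms_level %in% c(1L, 2L), length(mz) == length(intensity))
  if (is.unsorted(mz, strictly = TRUE))
    stop("spectrum m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("negative intensities")
  if (ms_level == 2L && is.na(precursor_mz) && is.na(isolation_lower))
    stop("MS2 spectrum needs a precursor m/z (DDA) or isolation bounds (DIA)")
  structure(list(
    ms_level = as.integer(ms_level), rt = as.numeric(rt),
    mz = as.numeric(mz), intensity = as.numeric(intensity),
    precursor_mz = precursor_mz, precursor_intensity = precursor_intensity,
    isolation_lower = isolation_lower, isolation_upper = isolation_upper,
    collision_energy = collision_energy
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> MS%d rt=%.1fs peaks=%d", x$ms_level, x$rt, length(x$mz)))
  if (!is.na(x$precursor_mz)) cat(sprintf(" prec=%.4f", x$precursor_mz))
  if (!is.na(x$isolation_lower))
    cat(sprintf(" window=[%.1f,%.1f)", x$isolation_lower, x$isolation_upper))
  cat("\n")
  invisible(x)
}

#' Construct an acquisition run
#'
#' A run is a time-ordered sequence of spectra plus acquisition metadata.
#' DIA runs carry the ordered SWATH window list (half-open `[lower, upper)`
#' bounds, one row per window).
#'
#' @param spectra List of [new_spectrum()] objects, sorted by `rt`.
#' @param acquisition_mode `"DDA"` or `"DIA"`.
#' @param swath_windows Two-column matrix (`lower`, `upper`) of SWATH window
#'   bounds; required for DIA.
#' @param run_id Optional run identifier string.
#' @return Object of class `ms_run`.
#' @export
new_run <- function(spectra, acquisition_mode = c("DDA", "DIA"),
                    swath_windows = NULL, run_id = "run1") {
  acquisition_mode <- match.arg(acquisition_mode)
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (is.unsorted(rts)) stop("spectra must be sorted by retention time")
  if (acquisition_mode == "DIA") {
    if (is.null(swath_windows)) stop("DIA run requires swath_windows")
    swath_windows <- as.matrix(swath_windows)
    colnames(swath_windows) <- c("lower", "upper")
    if (any(swath_windows[, 2] <= swath_windows[, 1]))
      stop("swath window upper bound must exceed lower bound")
  }
  structure(list(spectra = spectra, acquisition_mode = acquisition_mode,
                 swath_windows = swath_windows, run_id = run_id),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat(sprintf("<ms_run %s> %s: %d spectra (%d MS1, %d MS2)",
              x$run_id, x$acquisition_mode, length(lv), sum(lv == 1), sum(lv == 2)))
  if (!is.null(x$swath_windows))
    cat(sprintf(", %d SWATH windows", nrow(x$swath_windows)))
  cat("\n")
  invisible(x)
}

ms_levels <- function(run) vapply(run$spectra, `[[`, integer(1), "ms_level")
spectrum_rts <- function(run) vapply(run$spectra, `[[`, numeric(1), "rt")
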