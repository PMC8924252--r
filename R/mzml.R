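# mzML reading and writing, backed by mzR (proteowizard bindings).

#' Read a centroided mzML file
#'
#' Profile-mode spectra are rejected: the workflow operates on centroided
#' peak lists only. For DIA files the SWATH window list is inferred from the
#' isolation bounds of the first full cycle (the MS2 windows seen before the
#' first window repeats).
#'
#' @param path Path to an mzML file.
#' @return An [new_run()] object.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop("malformed mzML: ", conditionMessage(e)))
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0) stop("malformed mzML: file contains no spectra")
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("unsupported data: profile-mode spectra (centroid first)")
  pk <- mzR::peaks(handle)
  if (nrow(hdr) == 1) pk <- list(pk)
  has_iso <- "isolationWindowTargetMZ" %in% names(hdr)
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pk[[i]]
    o <- order(p[, 1])
    lvl <- hdr$msLevel[i]
    iso_lo <- iso_hi <- NA_real_
    if (lvl == 2L && has_iso && !is.na(hdr$isolationWindowTargetMZ[i])) {
      iso_lo <- hdr$isolationWindowTargetMZ[i] - hdr$isolationWindowLowerOffset[i]
      iso_hi <- hdr$isolationWindowTargetMZ[i] + hdr$isolationWindowUpperOffset[i]
    }
    prec <- if (lvl == 2L && !is.na(hdr$precursorMZ[i]) && hdr$precursorMZ[i] > 0)
      hdr$precursorMZ[i] else NA_real_
    new_spectrum(
      ms_level = lvl, rt = hdr$retentionTime[i],
      mz = p[o, 1], intensity = p[o, 2],
      precursor_mz = prec,
      precursor_intensity = if (lvl == 2L) hdr$precursorIntensity[i] else NA_real_,
      isolation_lower = iso_lo, isolation_upper = iso_hi
    )
  })
  windows <- infer_swath_windows(spectra)
  mode <- if (is.null(windows)) "DDA" else "DIA"
  new_run(spectra, acquisition_mode = mode, swath_windows = windows,
          run_id = sub("\\.mzML$", "", basename(path), ignore.case = TRUE))
}

# SWATH windows from the isolation bounds of the first full cycle; NULL for
# DDA files (no MS2 isolation bounds present).
infer_swath_windows <- function(spectra) {
  lv <- vapply(spectra, `[[`, integer(1), "ms_level")
  ms2 <- spectra[lv == 2L]
  if (length(ms2) == 0) return(NULL)
  lo <- vapply(ms2, `[[`, numeric(1), "isolation_lower")
  hi <- vapply(ms2, `[[`, numeric(1), "isolation_upper")
  if (all(is.na(lo))) return(NULL)
  keys <- sprintf("%.4f-%.4f", lo, hi)
  first_cycle <- which(duplicated(keys))[1]
  n <- if (is.na(first_cycle)) length(keys) else first_cycle - 1
  cbind(lower = lo[seq_len(n)], upper = hi[seq_len(n)])
}

#' Write a run to mzML
#'
#' @param run An [new_run()] object.
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  sp <- run$spectra
  n <- length(sp)
  if (n == 0) stop("cannot write an empty run")
  num <- function(field) vapply(sp, function(s) as.numeric(s[[field]]), numeric(1))
  lvl <- vapply(sp, `[[`, integer(1), "ms_level")
  npk <- vapply(sp, function(s) length(s$mz), integer(1))
  iso_lo <- num("isolation_lower"); iso_hi <- num("isolation_upper")
  prec <- num("precursor_mz")
  # DIA scans: mzR stores the isolation window as target +/- offsets.
  # DDA MS2 scans carry only a precursor m/z, no isolation window.
  target <- ifelse(!is.na(iso_lo), (iso_lo + iso_hi) / 2, NA_real_)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = vapply(sp, function(s) sum(s$intensity), numeric(1)),
    retentionTime = num("rt"),
    basePeakMZ = vapply(sp, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(sp, function(s)
      if (length(s$mz)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(sp, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(sp, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = rep(0L, n),
    precursorMZ = ifelse(lvl == 2L & !is.na(prec), prec, target),
    precursorCharge = ifelse(lvl == 2L, 1L, 0L),
    precursorIntensity = ifelse(lvl == 2L, num("precursor_intensity"), NA_real_),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = target,
    isolationWindowLowerOffset = ifelse(!is.na(iso_lo), target - iso_lo, NA_real_),
    isolationWindowUpperOffset = ifelse(!is.na(iso_hi), iso_hi - target, NA_real_),
    scanWindowLowerLimit = rep(NA_real_, n), scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  hdr$precursorIntensity[is.na(hdr$precursorIntensity)] <- 0
  hdr$precursorMZ[is.na(hdr$precursorMZ)] <- 0
  pks <- lapply(sp, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}
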