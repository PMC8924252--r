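# Targeted extraction from DIA runs: SWATH window assignment, XIC
# extraction, peak-group detection on the smoothed summed fragment trace,
# and peak-group sub-score computation for targets and decoys alike.

#' Assign a precursor to its SWATH window
#'
#' Windows are half-open `[lower, upper)`, so boundary values belong to the
#' upper window.
#'
#' @param precursor_mz Precursor m/z (Th).
#' @param swath_windows Two-column matrix of window bounds.
#' @return Window index (1-based). Errors if the m/z is not covered.
#' @export
assign_window <- function(precursor_mz, swath_windows) {
  w <- which(swath_windows[, 1] <= precursor_mz & precursor_mz < swath_windows[, 2])
  if (length(w) != 1)
    stop("precursor m/z ", precursor_mz, " not covered by any SWATH window")
  as.integer(w)
}

#' Build an extraction index for a DIA run
#'
#' Sorts all centroids of each SWATH window (and of the MS1 level) by m/z
#' with their scan positions, so that XIC extraction is a binary search plus
#' a grouped sum. Indexing once per run makes extraction of many assays
#' cheap.
#'
#' @param run A DIA [new_run()].
#' @return Object of class `dia_index`.
#' @export
index_dia_run <- function(run) {
  stopifnot(run$acquisition_mode == "DIA")
  W <- run$swath_windows
  lv <- ms_levels(run)
  rts <- spectrum_rts(run)
  ms2_win <- rep(NA_integer_, length(run$spectra))
  for (i in which(lv == 2L)) {
    lo <- run$spectra[[i]]$isolation_lower
    ms2_win[i] <- which.min(abs(W[, 1] - lo))
  }
  build_level <- function(idx) {
    grid_rt <- rts[idx]
    pos_of <- integer(length(run$spectra))
    pos_of[idx] <- seq_along(idx)
    mz <- unlist(lapply(idx, function(i) run$spectra[[i]]$mz))
    int <- unlist(lapply(idx, function(i) run$spectra[[i]]$intensity))
    scan <- rep(pos_of[idx], vapply(idx, function(i)
      length(run$spectra[[i]]$mz), integer(1)))
    o <- order(mz)
    list(grid_rt = grid_rt, mz = mz[o], intensity = int[o], scan = scan[o])
  }
  windows <- lapply(seq_len(nrow(W)), function(w) build_level(which(ms2_win == w)))
  ms1 <- build_level(which(lv == 1L))
  structure(list(run_id = run$run_id, swath_windows = W, ms1 = ms1,
                 windows = windows), class = "dia_index")
}

# XIC on an indexed level: summed intensity within +/- tol per scan,
# restricted to grid positions `keep`.
xic_from_level <- function(level, target_mz, ppm_tol, keep) {
  tol <- target_mz * ppm_tol * 1e-6
  lo <- findInterval(target_mz - tol, level$mz) + 1
  hi <- findInterval(target_mz + tol, level$mz)
  out <- numeric(length(keep))
  if (hi >= lo) {
    s <- level$scan[lo:hi]
    v <- level$intensity[lo:hi]
    inw <- s %in% keep
    if (any(inw)) {
      agg <- rowsum(v[inw], s[inw])
      pos <- match(as.integer(rownames(agg)), keep)
      out[pos] <- agg[, 1]
    }
  }
  out
}

#' Extract XICs for one assay
#'
#' One MS2 XIC per transition from the scans of the assay's SWATH window
#' (summed centroid intensity within `ppm_tol`), plus MS1 XICs for the
#' precursor and its first `n_isotopes - 1` isotope traces. All XICs of a
#' level share that level's scan grid, restricted to
#' `library_rt +/- rt_window`.
#'
#' @param index A [index_dia_run()] result (or a DIA run, indexed on the
#'   fly).
#' @param group A [transition_group()].
#' @param rt_window Half-width of the extraction window (seconds).
#' @param ppm_tol Extraction tolerance (ppm).
#' @param n_isotopes Number of MS1 isotope traces including the monoisotopic.
#' @return List with `ms2` (list of chromatograms: `rt`, `intensity`,
#'   `target_mz`, `level`, `role`) and `ms1` (same structure).
#' @export
extract_xics <- function(index, group, rt_window = 60, ppm_tol = 25,
                         n_isotopes = 3) {
  if (inherits(index, "ms_run")) index <- index_dia_run(index)
  w <- assign_window(group$precursor_mz, index$swath_windows)
  level <- index$windows[[w]]
  keep2 <- which(abs(level$grid_rt - group$library_rt) <= rt_window)
  ms2 <- lapply(seq_len(nrow(group$transitions)), function(j) {
    list(rt = level$grid_rt[keep2],
         intensity = xic_from_level(level, group$transitions$fragment_mz[j],
                                    ppm_tol, keep2),
         target_mz = group$transitions$fragment_mz[j], level = "MS2",
         role = sprintf("fragment_%d", j))
  })
  keep1 <- which(abs(index$ms1$grid_rt - group$library_rt) <= rt_window)
  ms1 <- lapply(seq_len(n_isotopes), function(k) {
    tmz <- group$precursor_mz + (k - 1) * ISOTOPE_SPACING
    list(rt = index$ms1$grid_rt[keep1],
         intensity = xic_from_level(index$ms1, tmz, ppm_tol, keep1),
         target_mz = tmz, level = "MS1",
         role = if (k == 1) "precursor" else sprintf("isotope_%d", k - 1))
  })
  list(ms2 = ms2, ms1 = ms1)
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0 || length(x) < 3) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
}

trapezoid <- function(t, y) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

#' Detect peak groups on extracted chromatograms
#'
#' Peaks are picked on the Gaussian-smoothed summed MS2 trace: local maxima,
#' strongest first, up to `max_rank`, with boundaries at the nearest local
#' minima (or where the smoothed trace falls below 1% of the apex).
#' Trapezoidal areas per transition and for the precursor trace are computed
#' within the boundaries.
#'
#' @param xics [extract_xics()] result.
#' @param smoothing_sigma Gaussian smoothing width in scans.
#' @param max_rank Maximum number of peak groups returned.
#' @return List of peak groups: `rt_apex`, `rt_start`, `rt_end`,
#'   `apex_intensity`, `transition_areas`, `precursor_area`,
#'   `boundary_idx` (MS2 scan index range), `rank` (by apex intensity).
#' @export
find_peak_groups <- function(xics, smoothing_sigma = 2, max_rank = 5) {
  stopifnot(length(xics$ms2) >= 1)
  rt <- xics$ms2[[1]]$rt
  n <- length(rt)
  if (n < 3) return(list())
  total <- Reduce(`+`, lapply(xics$ms2, `[[`, "intensity"))
  sm <- as.numeric(gaussian_smooth(total, smoothing_sigma))
  if (all(sm <= 0)) return(list())
  interior <- 2:(n - 1)
  is_max <- sm[interior] > sm[interior - 1] & sm[interior] >= sm[interior + 1] &
    sm[interior] > 0
  apexes <- interior[is_max]
  if (length(apexes) == 0) return(list())
  apexes <- apexes[order(sm[apexes], decreasing = TRUE)]
  apexes <- apexes[seq_len(min(max_rank, length(apexes)))]
  groups <- list()
  for (a in apexes) {
    floor_lvl <- 0.01 * sm[a]
    # walk downhill from the apex to the nearest local minimum or the 1%
    # floor, whichever comes first
    b0 <- a
    while (b0 > 1 && sm[b0 - 1] <= sm[b0] && sm[b0] > floor_lvl) b0 <- b0 - 1
    b1 <- a
    while (b1 < n && sm[b1 + 1] <= sm[b1] && sm[b1] > floor_lvl) b1 <- b1 + 1
    if (b0 >= a || b1 <= a) next
    areas <- vapply(xics$ms2, function(ch)
      trapezoid(rt[b0:b1], ch$intensity[b0:b1]), numeric(1))
    prec_area <- 0
    if (length(xics$ms1) > 0 && length(xics$ms1[[1]]$rt) >= 2) {
      m1 <- xics$ms1[[1]]
      in_b <- m1$rt >= rt[b0] & m1$rt <= rt[b1]
      if (sum(in_b) >= 2) prec_area <- trapezoid(m1$rt[in_b], m1$intensity[in_b])
    }
    groups[[length(groups) + 1]] <- list(
      rt_apex = rt[a], rt_start = rt[b0], rt_end = rt[b1],
      apex_intensity = sm[a], transition_areas = areas,
      precursor_area = prec_area, boundary_idx = c(b0, b1))
  }
  for (i in seq_along(groups)) groups[[i]]$rank <- i
  groups
}

# Normalized cross-correlation of two traces over integer shifts.
# Returns best shift and the correlation value at it.
best_xcorr <- function(x, y, max_shift = 10) {
  cx <- x - mean(x); cy <- y - mean(y)
  nx <- sqrt(sum(cx^2)); ny <- sqrt(sum(cy^2))
  if (nx == 0 || ny == 0) return(list(shift = 0, value = 0))
  cx <- cx / nx; cy <- cy / ny
  n <- length(x)
  shifts <- -min(max_shift, n - 1):min(max_shift, n - 1)
  vals <- vapply(shifts, function(d) {
    if (d >= 0) sum(cx[seq_len(n - d)] * cy[seq_len(n - d) + d])
    else sum(cx[seq_len(n + d) - d] * cy[seq_len(n + d)])
  }, numeric(1))
  k <- which.max(vals)
  list(shift = shifts[k], value = vals[k])
}

#' Score a peak group
#'
#' Computes the sub-score vector used for target-decoy discrimination,
#' within the peak boundaries:
#' \itemize{
#' \item `xcorr_coelution`: mean + sd of the |best-alignment shift| over all
#'   transition pairs (scans; 0 is perfect co-elution).
#' \item `xcorr_shape`: mean of the maximal normalized cross-correlation
#'   over transition pairs (1 is identical shape).
#' \item `library_corr`: Pearson correlation between library intensities and
#'   measured transition areas.
#' \item `sn`: log of the median apex/noise ratio over transitions, noise
#'   being 1.4826 * MAD of the trace outside the boundaries.
#' \item `ms1_isotope_corr`: Pearson correlation between measured isotope
#'   trace areas and the formula's expected isotope pattern.
#' \item `ms1_coelution`: |best shift| between the precursor trace
#'   (interpolated onto the MS2 grid) and the summed MS2 trace.
#' }
#' Pairwise scores fall back to neutral defaults when the group has fewer
#' than two transitions.
#'
#' @param pg One peak group from [find_peak_groups()].
#' @param xics The [extract_xics()] result the group was found on.
#' @param group The assay.
#' @param max_shift Cross-correlation shift search bound (scans).
#' @return `pg` with a named `scores` vector added.
#' @export
score_peak_group <- function(pg, xics, group, max_shift = 10) {
  b <- pg$boundary_idx
  seg <- lapply(xics$ms2, function(ch) ch$intensity[b[1]:b[2]])
  n_tr <- length(seg)
  if (n_tr >= 2) {
    shifts <- c(); shapes <- c()
    for (i in 1:(n_tr - 1)) for (j in (i + 1):n_tr) {
      bx <- best_xcorr(seg[[i]], seg[[j]], max_shift)
      shifts <- c(shifts, abs(bx$shift)); shapes <- c(shapes, bx$value)
    }
    xcorr_coelution <- mean(shifts) + (if (length(shifts) > 1) stats::sd(shifts) else 0)
    xcorr_shape <- mean(shapes)
  } else {
    xcorr_coelution <- 0; xcorr_shape <- 0
  }
  lib <- group$transitions$library_intensity
  library_corr <- if (n_tr >= 2 && stats::sd(lib) > 0 &&
                      stats::sd(pg$transition_areas) > 0)
    stats::cor(lib, pg$transition_areas) else 0
  rt <- xics$ms2[[1]]$rt
  outside <- setdiff(seq_along(rt), b[1]:b[2])
  snr <- vapply(seq_len(n_tr), function(j) {
    apex <- max(xics$ms2[[j]]$intensity[b[1]:b[2]])
    noise <- if (length(outside) >= 3)
      1.4826 * stats::mad(xics$ms2[[j]]$intensity[outside], constant = 1) else 0
    # intensities are counts: one count is the physical noise floor
    max(apex, 1) / max(noise, 1)
  }, numeric(1))
  sn <- log(stats::median(snr))
  iso_areas <- vapply(xics$ms1, function(ch) {
    in_b <- ch$rt >= pg$rt_start & ch$rt <= pg$rt_end
    if (sum(in_b) >= 2) trapezoid(ch$rt[in_b], ch$intensity[in_b]) else 0
  }, numeric(1))
  ms1_isotope_corr <- 0
  if (!is.na(group$formula) && length(iso_areas) >= 3 && stats::sd(iso_areas) > 0) {
    expected <- isotope_pattern(group$formula, length(iso_areas))
    if (stats::sd(expected) > 0)
      ms1_isotope_corr <- stats::cor(iso_areas, expected)
  }
  ms1_coelution <- 0
  if (length(xics$ms1) > 0 && length(xics$ms1[[1]]$rt) >= 2) {
    total <- Reduce(`+`, seg)
    m1 <- xics$ms1[[1]]
    prec_on_ms2 <- stats::approx(m1$rt, m1$intensity, xout = rt[b[1]:b[2]],
                                 rule = 2)$y
    ms1_coelution <- abs(best_xcorr(total, prec_on_ms2, max_shift)$shift)
  }
  pg$scores <- c(xcorr_coelution = xcorr_coelution, xcorr_shape = xcorr_shape,
                 library_corr = library_corr, sn = sn,
                 ms1_isotope_corr = ms1_isotope_corr,
                 ms1_coelution = ms1_coelution)
  pg
}

#' Extract and score peak groups for a library over DIA runs
#'
#' Runs [extract_xics()], [find_peak_groups()] and [score_peak_group()] for
#' every assay in every run and collects one row per peak group. Ranks are
#' provisional (apex intensity); statistical validation re-ranks by d-score.
#'
#' @param runs A DIA run or list of DIA runs.
#' @param library List of transition groups (targets and decoys).
#' @param params Named list overriding `rt_window` (60 s), `ppm_tol` (25),
#'   `n_isotopes` (3), `smoothing_sigma` (2 scans), `max_rank` (5),
#'   `max_shift` (10 scans).
#' @return Data frame with identification columns (`run_id`, `group_id`,
#'   `compound_name`, `adduct`, `is_decoy`, `rank`), peak geometry
#'   (`rt_apex`, `rt_start`, `rt_end`), quantities (`precursor_area`,
#'   `total_area`, `apex_intensity`) and one column per sub-score.
#' @export
extract_peak_groups <- function(runs, library, params = list()) {
  p <- utils::modifyList(list(rt_window = 60, ppm_tol = 25, n_isotopes = 3,
                              smoothing_sigma = 2, max_rank = 5,
                              max_shift = 10), params)
  if (inherits(runs, "ms_run")) runs <- list(runs)
  rows <- list()
  for (run in runs) {
    idx <- index_dia_run(run)
    for (g in library) {
      xics <- extract_xics(idx, g, p$rt_window, p$ppm_tol, p$n_isotopes)
      pgs <- find_peak_groups(xics, p$smoothing_sigma, p$max_rank)
      for (pg in pgs) {
        pg <- score_peak_group(pg, xics, g, p$max_shift)
        rows[[length(rows) + 1]] <- data.frame(
          run_id = idx$run_id, group_id = g$group_id,
          compound_name = g$compound_name, adduct = g$adduct,
          is_decoy = g$is_decoy, rank = pg$rank, rt_apex = pg$rt_apex,
          rt_start = pg$rt_start, rt_end = pg$rt_end,
          precursor_area = pg$precursor_area,
          total_area = sum(pg$transition_areas),
          apex_intensity = pg$apex_intensity,
          t(pg$scores), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) stop("no peak groups found")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
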