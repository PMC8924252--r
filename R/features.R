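# Candidate identification on DDA runs: mass-trace feature detection,
# isotope-trace filtering, adduct grouping, accurate-mass search, precursor
# correction and MS2-to-feature mapping.
#
# Feature tables are plain data frames with list-columns for per-feature
# formula candidates and mapped MS2 spectrum indices.

empty_feature_table <- function() {
  data.frame(feature_id = integer(0), mz = numeric(0), rt_apex = numeric(0),
             rt_start = numeric(0), rt_end = numeric(0), intensity = numeric(0),
             area = numeric(0), n_isotope_traces = integer(0),
             charge = integer(0), adduct = character(0),
             neutral_mass = numeric(0), stringsAsFactors = FALSE)
}

#' Detect features in a DDA run
#'
#' Mass traces are built by greedily linking MS1 centroids across
#' consecutive scans (nearest m/z within `ppm_tol`, gap tolerance one scan).
#' Traces shorter than `min_scans` scans or below `min_intensity` at apex
#' are dropped. Co-eluting traces spaced by the 13C isotope interval
#' (1.003355/charge Th, charge 1) are merged into one feature whose m/z is
#' the monoisotopic trace centroid and whose `n_isotope_traces` counts the
#' chain length.
#'
#' @param run A DDA [new_run()].
#' @param ppm_tol Trace-linking tolerance (ppm).
#' @param min_scans Minimum trace length in scans.
#' @param min_intensity Minimum apex intensity.
#' @return Feature data frame with list-columns `formula_candidates` and
#'   `ms2_idx`.
#' @export
detect_features <- function(run, ppm_tol = 10, min_scans = 5, min_intensity = 0) {
  lv <- ms_levels(run)
  ms1_idx <- which(lv == 1L)
  if (length(ms1_idx) == 0) stop("run has no MS1 scans")
  scans <- run$spectra[ms1_idx]
  n_scans <- length(scans)
  traces <- list()      # closed traces
  active <- list()      # each: list(mz_sum_w, w, last_mz, last_scan, scan, mz, int)
  for (s in seq_len(n_scans)) {
    sp <- scans[[s]]
    if (length(active) > 0) {
      last_mz <- vapply(active, `[[`, numeric(1), "centroid")
      last_scan <- vapply(active, `[[`, numeric(1), "last_scan")
    } else {
      last_mz <- numeric(0)
      last_scan <- numeric(0)
    }
    taken <- rep(FALSE, length(active))
    for (j in order(sp$intensity, decreasing = TRUE)) {
      mzj <- sp$mz[j]
      if (length(active) > 0) {
        # link against the running weighted centroid, not the last peak:
        # chaining to the previous peak random-walks under m/z jitter
        ok <- !taken & last_scan >= s - 2 &
          abs(mzj - last_mz) / mzj * 1e6 <= ppm_tol
        cand <- which(ok)
      } else cand <- integer(0)
      if (length(cand) > 0) {
        k <- cand[which.min(abs(mzj - last_mz[cand]))]
        tr <- active[[k]]
        tr$scan <- c(tr$scan, s); tr$mz <- c(tr$mz, mzj)
        tr$int <- c(tr$int, sp$intensity[j])
        tr$centroid <- sum(tr$mz * tr$int) / sum(tr$int)
        tr$last_scan <- s
        active[[k]] <- tr
        taken[k] <- TRUE
        last_mz[k] <- tr$centroid
      } else {
        active[[length(active) + 1]] <- list(centroid = mzj, last_scan = s,
                                             scan = s, mz = mzj,
                                             int = sp$intensity[j])
        taken <- c(taken, TRUE)
        last_mz <- c(last_mz, mzj); last_scan <- c(last_scan, s)
      }
    }
    stale <- which(vapply(active, `[[`, numeric(1), "last_scan") < s - 1)
    if (length(stale) > 0) {
      traces <- c(traces, active[stale])
      active <- active[-stale]
    }
  }
  traces <- c(traces, active)
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  traces <- Filter(function(tr)
    length(tr$scan) >= min_scans && max(tr$int) >= min_intensity, traces)
  if (length(traces) == 0) {
    ft <- empty_feature_table()
    ft$formula_candidates <- list(); ft$ms2_idx <- list()
    return(ft)
  }
  tr_tab <- data.frame(
    mz = vapply(traces, function(tr) sum(tr$mz * tr$int) / sum(tr$int), numeric(1)),
    rt_apex = vapply(traces, function(tr) rts[tr$scan[which.max(tr$int)]], numeric(1)),
    rt_start = vapply(traces, function(tr) rts[min(tr$scan)], numeric(1)),
    rt_end = vapply(traces, function(tr) rts[max(tr$scan)], numeric(1)),
    intensity = vapply(traces, function(tr) max(tr$int), numeric(1)),
    area = vapply(traces, function(tr) {
      t <- rts[tr$scan]
      if (length(t) < 2) return(0)
      sum(diff(t) * (head(tr$int, -1) + tr$int[-1]) / 2)
    }, numeric(1)))
  # isotope chaining: mono trace + partners at +k * 1.003355 Th, co-eluting
  o <- order(tr_tab$mz)
  assigned <- rep(FALSE, nrow(tr_tab))
  feats <- list()
  scan_dt <- if (length(rts) > 1) stats::median(diff(rts)) else 1
  for (i in o) {
    if (assigned[i]) next
    chain <- i
    assigned[i] <- TRUE
    k <- 1
    repeat {
      target <- tr_tab$mz[i] + k * ISOTOPE_SPACING
      tol_th <- 2 * target * ppm_tol * 1e-6
      cand <- which(!assigned & abs(tr_tab$mz - target) <= tol_th &
                      abs(tr_tab$rt_apex - tr_tab$rt_apex[i]) <= 3 * scan_dt)
      if (length(cand) == 0) break
      j <- cand[which.min(abs(tr_tab$mz[cand] - target))]
      chain <- c(chain, j)
      assigned[j] <- TRUE
      k <- k + 1
    }
    feats[[length(feats) + 1]] <- data.frame(
      mz = tr_tab$mz[i], rt_apex = tr_tab$rt_apex[i],
      rt_start = tr_tab$rt_start[i], rt_end = tr_tab$rt_end[i],
      intensity = tr_tab$intensity[i], area = tr_tab$area[i],
      n_isotope_traces = length(chain), charge = 1L,
      adduct = NA_character_, neutral_mass = NA_real_)
  }
  ft <- do.call(rbind, feats)
  ft <- ft[order(ft$rt_apex, ft$mz), , drop = FALSE]
  ft$feature_id <- seq_len(nrow(ft))
  rownames(ft) <- NULL
  ft$formula_candidates <- replicate(nrow(ft), NULL, simplify = FALSE)
  ft$ms2_idx <- replicate(nrow(ft), integer(0), simplify = FALSE)
  ft
}

#' Filter features by isotope-trace count
#'
#' @param features Feature table from [detect_features()].
#' @param min_traces Minimum `n_isotope_traces` to keep.
#' @return Subset of `features`, order preserved.
#' @export
filter_by_isotope_traces <- function(features, min_traces = 2) {
  features[features$n_isotope_traces >= min_traces, , drop = FALSE]
}

#' Group co-eluting features into adduct groups
#'
#' Features whose apex RTs differ by at most `rt_tol` and whose m/z
#' difference matches a difference of two adduct shifts within `ppm_tol` are
#' grouped; each group is assigned one neutral mass and per-feature adduct
#' labels. Ungrouped features default to `[M+H]+`.
#'
#' @param features Feature table.
#' @param rt_tol Co-elution tolerance (seconds).
#' @param ppm_tol Mass tolerance on the shift difference (ppm of the larger
#'   m/z).
#' @param adducts Adduct table (see [adduct_table()]).
#' @return Feature table with `adduct` and `neutral_mass` filled in.
#' @export
group_adducts <- function(features, rt_tol = 10, ppm_tol = 10,
                          adducts = adduct_table()) {
  n <- nrow(features)
  if (n == 0) return(features)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pair_label <- vector("list", n)  # per feature: named ppm-error per adduct evidence
  for (i in seq_len(n)) pair_label[[i]] <- character(0)
  shifts <- adducts$shift
  names(shifts) <- adducts$adduct
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(features$rt_apex[i] - features$rt_apex[j]) > rt_tol) next
    dmz <- features$mz[j] - features$mz[i]
    for (a in seq_along(shifts)) for (b in seq_along(shifts)) {
      if (a == b) next
      dsh <- shifts[b] - shifts[a]
      if (dsh <= 0) next
      if (abs(abs(dmz) - dsh) / max(features$mz[i], features$mz[j]) * 1e6 <= ppm_tol) {
        lo <- if (dmz > 0) i else j
        hi <- if (dmz > 0) j else i
        parent[find(hi)] <- find(lo)
        pair_label[[lo]] <- c(pair_label[[lo]], names(shifts)[a])
        pair_label[[hi]] <- c(pair_label[[hi]], names(shifts)[b])
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  for (g in unique(root)) {
    members <- which(root == g)
    for (i in members) {
      lab <- pair_label[[i]]
      features$adduct[i] <- if (length(lab) > 0)
        names(sort(table(lab), decreasing = TRUE))[1] else "[M+H]+"
      features$neutral_mass[i] <- neutral_mass_from_mz(features$mz[i],
                                                       features$adduct[i])
    }
    features$neutral_mass[members] <- mean(features$neutral_mass[members])
  }
  features
}

#' Accurate-mass search against a compound database
#'
#' For each feature the neutral mass (inverse of the adduct m/z) is matched
#' against the database; all records within `ppm_tol` are attached as
#' formula candidates, sorted by absolute ppm error.
#'
#' @param features Feature table with adducts assigned.
#' @param compound_db Data frame with columns `name`, `formula` and
#'   optionally `rt_sec`.
#' @param ppm_tol Search tolerance (ppm).
#' @return Feature table with the `formula_candidates` list-column filled
#'   (data frames with `name`, `formula`, `ppm_error`).
#' @export
accurate_mass_search <- function(features, compound_db, ppm_tol = 5) {
  if (nrow(compound_db) == 0) stop("empty compound database")
  db_mass <- vapply(compound_db$formula, monoisotopic_mass, numeric(1))
  for (i in seq_len(nrow(features))) {
    adduct <- if (is.na(features$adduct[i])) "[M+H]+" else features$adduct[i]
    nm <- neutral_mass_from_mz(features$mz[i], adduct)
    ppm <- (nm - db_mass) / db_mass * 1e6
    hit <- which(abs(ppm) <= ppm_tol)
    if (length(hit) > 0) {
      o <- hit[order(abs(ppm[hit]))]
      features$formula_candidates[[i]] <- data.frame(
        name = compound_db$name[o], formula = compound_db$formula[o],
        ppm_error = ppm[o], stringsAsFactors = FALSE)
    }
  }
  features
}

#' Snap recorded MS2 precursors to the survey-scan centroid
#'
#' Replaces each DDA MS2 precursor m/z by the nearest centroid of the
#' preceding MS1 scan within `tol` Th and sets the precursor intensity to
#' that centroid's intensity. Spectra without a matching centroid are
#' flagged (`precursor_corrected = FALSE`) and left unchanged.
#'
#' @param run A DDA run.
#' @param tol Snap tolerance (Th).
#' @return The run with corrected precursors.
#' @export
correct_precursors <- function(run, tol = 0.05) {
  lv <- ms_levels(run)
  last_ms1 <- 0L
  for (i in seq_along(run$spectra)) {
    if (lv[i] == 1L) { last_ms1 <- i; next }
    sp <- run$spectra[[i]]
    sp$precursor_corrected <- FALSE
    if (last_ms1 > 0L && !is.na(sp$precursor_mz)) {
      ms1 <- run$spectra[[last_ms1]]
      if (length(ms1$mz) > 0) {
        d <- abs(ms1$mz - sp$precursor_mz)
        k <- which.min(d)
        if (d[k] <= tol) {
          sp$precursor_mz <- ms1$mz[k]
          sp$precursor_intensity <- ms1$intensity[k]
          sp$precursor_corrected <- TRUE
        }
      }
    }
    run$spectra[[i]] <- sp
  }
  run
}

#' Assign MS2 spectra to features
#'
#' An MS2 spectrum maps to a feature iff its precursor m/z is within
#' `ppm_tol` of the feature m/z and its RT lies within the feature's RT
#' bounds. A spectrum maps to at most one feature: the smallest ppm distance
#' wins, ties go to the higher-intensity feature.
#'
#' @param features Feature table.
#' @param run The (precursor-corrected) DDA run.
#' @param ppm_tol Mapping tolerance (ppm).
#' @return Feature table with the `ms2_idx` list-column holding spectrum
#'   indices into `run$spectra`.
#' @export
map_ms2_to_features <- function(features, run, ppm_tol = 10) {
  lv <- ms_levels(run)
  for (i in which(lv == 2L)) {
    sp <- run$spectra[[i]]
    if (is.na(sp$precursor_mz)) next
    ppm <- abs(sp$precursor_mz - features$mz) / features$mz * 1e6
    ok <- which(ppm <= ppm_tol & features$rt_start <= sp$rt &
                  sp$rt <= features$rt_end)
    if (length(ok) == 0) next
    best <- ok[order(ppm[ok], -features$intensity[ok])][1]
    features$ms2_idx[[best]] <- c(features$ms2_idx[[best]], i)
  }
  features
}
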