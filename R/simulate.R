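# Synthetic DDA/DIA data generator.
#
# Emulates the acquisition scheme the pipeline assumes: DDA runs with MS1
# survey scans plus precursor-selected MS2 spectra, and DIA runs cycling one
# MS1 survey scan followed by a fixed series of SWATH windows. Chromatography
# is Gaussian; the dilution series is multiplicative with lognormal replicate
# noise; masses carry ppm-scale jitter; spectra carry exponential-intensity
# noise peaks.

# Neutral-loss pool used to derive fragment templates. Losses are applied
# cumulatively, so every fragment formula is a subformula of the precursor.
LOSS_POOL <- c("H2O", "CO", "CO2", "CH2O", "C2H4", "C2H2", "CH3", "C3H6",
               "C2H4O", "H2", "C2H2O", "CH4", "C4H8", "C2H6")
LOSS_POOL_N <- c("NH3", "HCN", "CH3N", "CH5N")

#' Define a simulated compound
#'
#' @param name Compound name.
#' @param formula Molecular formula of the neutral compound.
#' @param adduct Adduct label under which the compound ionizes.
#' @param rt Elution apex (seconds).
#' @param peak_sigma Gaussian chromatographic peak width (seconds).
#' @param base_intensity Apex intensity at the highest concentration (counts).
#' @param fragment_template Data frame with columns `formula` (fragment
#'   subformula string) and `rel_intensity` in (0, 1], max-normalized.
#' @return Object of class `sim_compound`.
#' @export
sim_compound <- function(name, formula, adduct = "[M+H]+", rt, peak_sigma = 4,
                         base_intensity = 1e5, fragment_template) {
  formula <- parse_formula(formula)
  stopifnot(is.data.frame(fragment_template),
            all(c("formula", "rel_intensity") %in% names(fragment_template)))
  ok <- vapply(fragment_template$formula, function(f)
    is_subformula(f, formula), logical(1))
  if (!all(ok)) stop("fragment template formulas must be subformulas of ",
                     formula_to_string(formula))
  fragment_template$rel_intensity <-
    fragment_template$rel_intensity / max(fragment_template$rel_intensity)
  structure(list(name = name, formula = formula, adduct = adduct, rt = rt,
                 peak_sigma = peak_sigma, base_intensity = base_intensity,
                 fragment_template = fragment_template),
            class = "sim_compound")
}

# Random fragment template: cumulative neutral losses from the precursor.
random_fragment_template <- function(formula, n_fragments, min_mass = 60) {
  formula <- parse_formula(formula)
  pool <- c(LOSS_POOL, if ("N" %in% names(formula)) LOSS_POOL_N)
  frags <- character(0)
  current <- formula
  guard <- 0
  while (length(frags) < n_fragments && guard < 200) {
    guard <- guard + 1
    cand_losses <- pool[vapply(pool, function(l) is_subformula(l, current), logical(1))]
    if (length(cand_losses) == 0) { current <- formula; next }
    loss <- sample(cand_losses, 1)
    nxt <- formula_subtract(current, loss)
    if (monoisotopic_mass(nxt) < min_mass) { current <- formula; next }
    key <- formula_to_string(nxt)
    if (!(key %in% frags)) frags <- c(frags, key)
    # sometimes restart from the precursor to branch the fragmentation
    current <- if (stats::runif(1) < 0.4) formula else nxt
  }
  if (length(frags) == 0) stop("could not derive fragments for ", formula_to_string(formula))
  rel <- sort(stats::runif(length(frags), 0.1, 1), decreasing = TRUE)
  data.frame(formula = frags, rel_intensity = rel / max(rel),
             stringsAsFactors = FALSE)
}

#' Generate a random set of simulated compounds
#'
#' Draws pesticide-like small-molecule formulas (C8-C24 with N/O/S/Cl
#' heteroatoms), spreads elution apexes evenly over the usable gradient and
#' derives fragment templates by cumulative neutral losses.
#'
#' @param n Number of compounds.
#' @param gradient_length Gradient length in seconds.
#' @param n_fragments Fragments per compound (recycled).
#' @param peak_sigma Peak width (seconds).
#' @param rt_margin Fraction of the gradient kept free at both ends.
#' @return List of [sim_compound()] objects. Uses the current RNG state;
#'   call `set.seed()` first for reproducibility.
#' @export
sim_compound_set <- function(n, gradient_length = 300, n_fragments = 5,
                             peak_sigma = 4, rt_margin = 0.12) {
  n_fragments <- rep_len(n_fragments, n)
  rts <- seq(rt_margin * gradient_length, (1 - rt_margin) * gradient_length,
             length.out = n) + stats::runif(n, -1, 1)
  lapply(seq_len(n), function(i) {
    repeat {
      C <- sample(8:18, 1)
      H <- sample(round(C * 1.1):round(C * 1.6), 1)
      f <- c(C = C, H = H,
             N = sample(0:3, 1, prob = c(0.4, 0.3, 0.2, 0.1)),
             O = sample(0:6, 1),
             S = sample(0:1, 1, prob = c(0.85, 0.15)),
             Cl = sample(0:2, 1, prob = c(0.7, 0.2, 0.1)))
      f <- parse_formula(f[f > 0])
      mz <- adduct_mz(monoisotopic_mass(f), "[M+H]+")
      if (mz > 150 && mz < 850 && rdbe(f) >= 0) break
    }
    tmpl <- random_fragment_template(f, n_fragments[i])
    sim_compound(name = sprintf("cmpd%03d", i), formula = f, adduct = "[M+H]+",
                 rt = rts[i], peak_sigma = peak_sigma,
                 base_intensity = 10^stats::runif(1, 5, 6),
                 fragment_template = tmpl)
  })
}

#' Define a simulation design
#'
#' The defaults encode the acquisition scheme the workflow targets: a 4-fold,
#' 10-step dilution series in triplicate (spanning more than five orders of
#' magnitude), SWATH cycles of one MS1 survey scan followed by eight fragment
#' windows tiling 100-900 Th, ppm-scale mass jitter, lognormal replicate
#' variation and exponential-intensity noise peaks.
#'
#' @param compounds List of [sim_compound()] objects.
#' @param n_dilutions Number of dilution steps.
#' @param dilution_factor Fold change between consecutive steps (> 1).
#' @param n_replicates Technical replicates per step.
#' @param gradient_length Run length (seconds).
#' @param ms1_interval Cycle time: seconds between consecutive MS1 survey
#'   scans; the SWATH scans of a cycle are spread evenly inside it.
#' @param swath_windows Two-column matrix of half-open `[lower, upper)`
#'   window bounds tiling the precursor range without overlap.
#' @param mass_jitter_ppm Gaussian m/z jitter (ppm, 1 sd).
#' @param intensity_cv Lognormal coefficient of variation applied per
#'   compound and replicate run.
#' @param noise_peaks_per_spectrum Spurious peaks added to every spectrum.
#' @param noise_intensity_mean Mean of the exponential noise-peak intensity.
#' @param seed Seed for all randomness in the simulated runs.
#' @return Object of class `sim_design`.
#' @export
sim_design <- function(compounds, n_dilutions = 10, dilution_factor = 4,
                       n_replicates = 3, gradient_length = 300,
                       ms1_interval = 1.5,
                       swath_windows = cbind(lower = seq(100, 800, by = 100),
                                             upper = seq(200, 900, by = 100)),
                       mass_jitter_ppm = 3, intensity_cv = 0.1,
                       noise_peaks_per_spectrum = 400,
                       noise_intensity_mean = 100, seed = 1) {
  stopifnot(dilution_factor > 1, n_dilutions >= 1, n_replicates >= 1)
  swath_windows <- as.matrix(swath_windows)
  colnames(swath_windows) <- c("lower", "upper")
  o <- order(swath_windows[, 1])
  swath_windows <- swath_windows[o, , drop = FALSE]
  if (nrow(swath_windows) > 1 &&
      any(abs(swath_windows[-nrow(swath_windows), 2] -
              swath_windows[-1, 1]) > 1e-9))
    stop("design error: SWATH windows must tile the range without gaps or overlap")
  for (cm in compounds) {
    mz <- adduct_mz(monoisotopic_mass(cm$formula), cm$adduct)
    if (mz < swath_windows[1, 1] || mz >= swath_windows[nrow(swath_windows), 2])
      stop("design error: precursor of ", cm$name, " outside the SWATH range")
  }
  structure(list(compounds = compounds, n_dilutions = n_dilutions,
                 dilution_factor = dilution_factor, n_replicates = n_replicates,
                 gradient_length = gradient_length, ms1_interval = ms1_interval,
                 swath_windows = swath_windows, mass_jitter_ppm = mass_jitter_ppm,
                 intensity_cv = intensity_cv,
                 noise_peaks_per_spectrum = noise_peaks_per_spectrum,
                 noise_intensity_mean = noise_intensity_mean, seed = seed),
            class = "sim_design")
}

# Per-compound precursor ion m/z and fragment ion m/z vector.
compound_ions <- function(cm) {
  prec <- adduct_mz(monoisotopic_mass(cm$formula), cm$adduct)
  frag <- vapply(cm$fragment_template$formula,
                 function(f) monoisotopic_mass(f) + PROTON_MASS, numeric(1))
  list(precursor_mz = prec, fragment_mz = unname(frag),
       rel = cm$fragment_template$rel_intensity)
}

jitter_mz <- function(mz, ppm) if (ppm == 0) mz else mz * (1 + stats::rnorm(length(mz), 0, ppm * 1e-6))

# Assemble spectra from a long (scan, mz, intensity) signal table plus noise.
# One global m/z sort; splitting by scan then yields per-spectrum peak lists
# already sorted by m/z.
assemble_spectra <- function(scan_idx, mz, intensity, scan_times, scan_meta,
                             design, noise_range) {
  n_scans <- length(scan_times)
  npn <- design$noise_peaks_per_spectrum
  if (npn > 0) {
    scan_idx <- c(scan_idx, rep(seq_len(n_scans), each = npn))
    mz <- c(mz, stats::runif(n_scans * npn, noise_range[1], noise_range[2]))
    intensity <- c(intensity, stats::rexp(n_scans * npn,
                                          1 / design$noise_intensity_mean))
  }
  keep <- intensity > 0
  scan_idx <- scan_idx[keep]; mz <- mz[keep]; intensity <- intensity[keep]
  o <- order(mz)
  f <- factor(scan_idx[o], levels = seq_len(n_scans))
  mz_by <- split(mz[o], f)
  int_by <- split(intensity[o], f)
  lapply(seq_len(n_scans), function(i) {
    m <- mz_by[[i]]; v <- int_by[[i]]
    if (anyDuplicated(m)) {           # merge exact m/z collisions
      v <- as.numeric(rowsum(v, m))
      m <- sort(unique(m))
    }
    list(mz = m, intensity = v, meta = scan_meta[i, ])
  })
}

#' Simulate a DDA run
#'
#' MS1 survey scans carry three-isotope envelopes (M, M+1, M+2 with
#' intensities from [isotope_pattern()]) for every eluting compound; each
#' compound whose Gaussian elution profile exceeds 5% of its apex at a survey
#' scan triggers an MS2 spectrum whose precursor m/z is the (jittered) adduct
#' m/z and whose peaks are the protonated fragment-template masses.
#'
#' @param design A [sim_design()].
#' @return List with elements `run` (an [new_run()], acquisition mode DDA)
#'   and `truth` (data frame: compound, adduct, formula, rt_sec,
#'   precursor_mz, n_ms2).
#' @export
simulate_dda <- function(design) {
  set.seed(design$seed)
  cms <- design$compounds
  ms1_times <- seq(0, design$gradient_length, by = design$ms1_interval)
  n1 <- length(ms1_times)
  sig <- list(scan = integer(0), mz = numeric(0), int = numeric(0))
  ms2_specs <- list()
  truth <- list()
  for (cm in cms) {
    ion <- compound_ions(cm)
    iso <- isotope_pattern(cm$formula, 3)
    idx <- which(abs(ms1_times - cm$rt) < 4 * cm$peak_sigma)
    h <- cm$base_intensity * exp(-(ms1_times[idx] - cm$rt)^2 / (2 * cm$peak_sigma^2))
    for (k in 0:2) {
      sig$scan <- c(sig$scan, idx)
      sig$mz <- c(sig$mz, jitter_mz(rep(ion$precursor_mz + k * ISOTOPE_SPACING,
                                        length(idx)), design$mass_jitter_ppm))
      sig$int <- c(sig$int, h * iso[k + 1])
    }
    # MS2 triggered after survey scans where the compound is above 5% apex
    trig <- idx[h >= 0.05 * cm$base_intensity]
    n_ms2 <- 0
    for (s in trig) {
      ht <- cm$base_intensity * exp(-(ms1_times[s] - cm$rt)^2 / (2 * cm$peak_sigma^2))
      fmz <- jitter_mz(ion$fragment_mz, design$mass_jitter_ppm)
      fint <- ion$rel * ht
      npn <- design$noise_peaks_per_spectrum
      if (npn > 0) {
        fmz <- c(fmz, stats::runif(npn, 50, 900))
        fint <- c(fint, stats::rexp(npn, 1 / design$noise_intensity_mean))
      }
      o <- order(fmz)
      ms2_specs[[length(ms2_specs) + 1]] <- list(
        rt = ms1_times[s] + design$ms1_interval * 0.4,
        mz = fmz[o], intensity = fint[o],
        precursor_mz = jitter_mz(ion$precursor_mz, design$mass_jitter_ppm),
        precursor_intensity = ht)
      n_ms2 <- n_ms2 + 1
    }
    truth[[length(truth) + 1]] <- data.frame(
      compound = cm$name, adduct = cm$adduct,
      formula = formula_to_string(cm$formula), rt_sec = cm$rt,
      precursor_mz = ion$precursor_mz, n_ms2 = n_ms2, stringsAsFactors = FALSE)
  }
  meta <- data.frame(i = seq_len(n1))
  ms1_list <- assemble_spectra(sig$scan, sig$mz, sig$int, ms1_times, meta,
                               design, noise_range = c(100, 1000))
  spectra <- c(
    lapply(seq_len(n1), function(i)
      new_spectrum(1L, ms1_times[i], ms1_list[[i]]$mz, ms1_list[[i]]$intensity)),
    lapply(ms2_specs, function(s)
      new_spectrum(2L, s$rt, s$mz, s$intensity, precursor_mz = s$precursor_mz,
                   precursor_intensity = s$precursor_intensity))
  )
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  run <- new_run(spectra[order(rts)], "DDA", run_id = "dda_run")
  list(run = run, truth = do.call(rbind, truth))
}

#' Simulate a DIA/SWATH dilution series
#'
#' Generates `n_dilutions * n_replicates` runs. Every cycle is one MS1 survey
#' scan followed by one scan per SWATH window; fragment signal of a compound
#' appears only in the window containing its precursor m/z. Each ion's
#' chromatogram is Gaussian with the compound's apex intensity scaled by
#' `dilution_factor^-(step-1)` and lognormal replicate noise with the
#' design's `intensity_cv`.
#'
#' @param design A [sim_design()].
#' @return List with `runs` (list of [new_run()] objects, DIA) and `truth`
#'   (data frame: compound, adduct, run_id, dilution_step, replicate, rt_sec,
#'   true_apex, true_area).
#' @export
simulate_dia <- function(design) {
  set.seed(design$seed + 1L)
  cms <- design$compounds
  W <- design$swath_windows
  nw <- nrow(W)
  cyc <- seq(0, design$gradient_length, by = design$ms1_interval)
  dt <- design$ms1_interval / (nw + 1)
  ions <- lapply(cms, compound_ions)
  winof <- vapply(ions, function(io) assign_window(io$precursor_mz, W), integer(1))
  sdlog <- sqrt(log(1 + design$intensity_cv^2))
  runs <- list()
  truth <- list()
  for (step in seq_len(design$n_dilutions)) {
    for (rep_i in seq_len(design$n_replicates)) {
      run_id <- sprintf("dia_s%02d_r%d", step, rep_i)
      dil <- design$dilution_factor^-(step - 1)
      repf <- if (design$intensity_cv > 0)
        stats::rlnorm(length(cms), -sdlog^2 / 2, sdlog) else rep(1, length(cms))
      # one spectrum stream per level/window
      specs <- vector("list", nw + 1)  # [[1]] = MS1, [[w+1]] = window w
      for (slot in seq_len(nw + 1)) {
        times <- cyc + (slot - 1) * dt
        parts_scan <- list(); parts_mz <- list(); parts_int <- list()
        for (ci in seq_along(cms)) {
          cm <- cms[[ci]]
          io <- ions[[ci]]
          scale <- cm$base_intensity * dil * repf[ci]
          idx <- which(abs(times - cm$rt) < 4 * cm$peak_sigma)
          if (length(idx) == 0) next
          h <- scale * exp(-(times[idx] - cm$rt)^2 / (2 * cm$peak_sigma^2))
          if (slot == 1) {
            iso <- isotope_pattern(cm$formula, 3)
            for (k in 0:2) {
              parts_scan[[length(parts_scan) + 1]] <- idx
              parts_mz[[length(parts_mz) + 1]] <-
                jitter_mz(rep(io$precursor_mz + k * ISOTOPE_SPACING, length(idx)),
                          design$mass_jitter_ppm)
              parts_int[[length(parts_int) + 1]] <- h * iso[k + 1]
            }
          } else if (winof[ci] == slot - 1) {
            for (j in seq_along(io$fragment_mz)) {
              parts_scan[[length(parts_scan) + 1]] <- idx
              parts_mz[[length(parts_mz) + 1]] <-
                jitter_mz(rep(io$fragment_mz[j], length(idx)),
                          design$mass_jitter_ppm)
              parts_int[[length(parts_int) + 1]] <- h * io$rel[j]
            }
          }
        }
        rng <- if (slot == 1) c(100, 1000) else c(50, 900)
        specs[[slot]] <- assemble_spectra(
          unlist(parts_scan) %||% integer(0), unlist(parts_mz) %||% numeric(0),
          unlist(parts_int) %||% numeric(0), times,
          data.frame(i = seq_along(times)), design, rng)
      }
      spectra <- vector("list", (nw + 1) * length(cyc))
      pos <- 1
      for (c_i in seq_along(cyc)) {
        sp <- specs[[1]][[c_i]]
        spectra[[pos]] <- new_spectrum(1L, cyc[c_i], sp$mz, sp$intensity)
        pos <- pos + 1
        for (w in seq_len(nw)) {
          sp <- specs[[w + 1]][[c_i]]
          spectra[[pos]] <- new_spectrum(
            2L, cyc[c_i] + w * dt, sp$mz, sp$intensity,
            isolation_lower = W[w, 1], isolation_upper = W[w, 2])
          pos <- pos + 1
        }
      }
      runs[[run_id]] <- new_run(spectra, "DIA", swath_windows = W, run_id = run_id)
      truth[[length(truth) + 1]] <- data.frame(
        compound = vapply(cms, `[[`, character(1), "name"),
        adduct = vapply(cms, `[[`, character(1), "adduct"),
        run_id = run_id, dilution_step = step, replicate = rep_i,
        rt_sec = vapply(cms, `[[`, numeric(1), "rt"),
        true_apex = vapply(seq_along(cms), function(ci)
          cms[[ci]]$base_intensity * dil * repf[ci], numeric(1)),
        true_area = vapply(seq_along(cms), function(ci)
          cms[[ci]]$base_intensity * dil * repf[ci] *
            cms[[ci]]$peak_sigma * sqrt(2 * pi), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  list(runs = runs, truth = do.call(rbind, truth))
}

#' Target assays straight from a simulation design
#'
#' Builds one target [transition_group()] per simulated compound from its
#' fragment template (top `n` fragments by relative intensity), together
#' with the fragmentation tree implied by the template. Useful for testing
#' extraction and scoring independently of DDA library construction.
#'
#' @param design A [sim_design()].
#' @param n Transitions per assay.
#' @param with_trees Also build the fragmentation trees (needed for
#'   re-rooting decoys; skip for plain assay lists).
#' @return List of transition groups; attribute `"trees"` holds the matching
#'   [build_tree()] results keyed by group_id (when `with_trees`).
#' @export
design_assays <- function(design, n = 3, with_trees = TRUE) {
  groups <- list()
  trees <- list()
  for (cm in design$compounds) {
    io <- compound_ions(cm)
    o <- order(cm$fragment_template$rel_intensity, decreasing = TRUE)
    take <- o[seq_len(min(n, length(o)))]
    gid <- paste0(cm$name, "_", cm$adduct)
    tr <- data.frame(fragment_mz = io$fragment_mz[take],
                     library_intensity = io$rel[take] / max(io$rel[take]),
                     fragment_formula = cm$fragment_template$formula[take],
                     stringsAsFactors = FALSE)
    groups[[gid]] <- transition_group(gid, cm$name, cm$formula, cm$adduct,
                                      io$precursor_mz, cm$rt, tr)
    if (with_trees) {
      spec <- new_spectrum(2L, cm$rt,
                           sort(io$fragment_mz),
                           cm$fragment_template$rel_intensity[order(io$fragment_mz)],
                           precursor_mz = io$precursor_mz)
      trees[[gid]] <- build_tree(cm$formula, spec, ppm_tol = 5, min_annotated = 1)
    }
  }
  attr(groups, "trees") <- trees
  groups
}

#' Assays for compounds never injected
#'
#' Generates `m` syntactically valid target assays whose precursor and
#' fragment m/z regions contain only noise in the simulated DIA runs: every
#' trace of an accepted assay is at least `min_ppm_distance` away from every
#' real precursor-isotope and fragment trace of the design.
#'
#' @param design A [sim_design()].
#' @param m Number of absent assays (>= 0).
#' @param n Transitions per assay.
#' @param min_ppm_distance Minimal allowed distance to any real trace (ppm).
#' @param with_trees Attach fragmentation trees (attribute `"trees"`), so
#'   that decoys for absent assays can be generated by re-rooting too.
#' @return List of transition groups (`is_decoy = FALSE`; they are targets,
#'   just absent from the sample). Deterministic given the design seed.
#' @export
make_absent_assays <- function(design, m, n = 3, min_ppm_distance = 50,
                               with_trees = TRUE) {
  if (m == 0) return(list())
  set.seed(design$seed + 7717L)
  real <- unlist(lapply(design$compounds, function(cm) {
    io <- compound_ions(cm)
    c(io$precursor_mz + 0:2 * ISOTOPE_SPACING, io$fragment_mz)
  }))
  out <- list()
  trees <- list()
  attempts <- 0
  while (length(out) < m && attempts < 80 * m) {
    attempts <- attempts + 1
    cand <- sim_compound_set(1, gradient_length = design$gradient_length,
                             n_fragments = max(n, 4))[[1]]
    io <- compound_ions(cand)
    traces <- c(io$precursor_mz + 0:2 * ISOTOPE_SPACING, io$fragment_mz)
    dmin <- min(vapply(traces, function(t)
      min(abs(t - real) / t * 1e6), numeric(1)))
    if (dmin <= min_ppm_distance) next
    gid <- sprintf("absent%03d_%s", length(out) + 1, cand$adduct)
    o <- order(cand$fragment_template$rel_intensity, decreasing = TRUE)
    take <- o[seq_len(min(n, length(o)))]
    rt <- stats::runif(1, 0.15, 0.85) * design$gradient_length
    out[[gid]] <- transition_group(
      gid, sub("_.*$", "", gid), cand$formula, cand$adduct, io$precursor_mz, rt,
      data.frame(fragment_mz = io$fragment_mz[take],
                 library_intensity = io$rel[take] / max(io$rel[take]),
                 fragment_formula = cand$fragment_template$formula[take],
                 stringsAsFactors = FALSE))
    if (with_trees) {
      o2 <- order(io$fragment_mz)
      spec <- new_spectrum(2L, rt, io$fragment_mz[o2],
                           cand$fragment_template$rel_intensity[o2],
                           precursor_mz = io$precursor_mz)
      trees[[gid]] <- build_tree(cand$formula, spec, ppm_tol = 5,
                                 min_annotated = 1)
    }
    real <- c(real, traces)   # keep absent assays mutually disjoint too
  }
  if (length(out) < m)
    stop("could not place ", m, " absent assays without m/z collisions")
  attr(out, "trees") <- trees
  out
}
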