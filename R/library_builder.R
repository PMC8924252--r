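# Assay library construction from DDA candidate features: candidate
# filtering, transition extraction from annotated trees, ambiguity
# resolution, collision-energy merging and the full build chain.

#' Filter candidate features for library construction
#'
#' Keeps features that have at least one formula candidate (MS1
#' identification) and at least one mapped MS2 spectrum with four or more
#' peaks (enough for fragment annotation). Drop counts per reason are
#' attached as attribute `"drop_report"`.
#'
#' @param features Feature table after MS2 mapping.
#' @param run The DDA run the `ms2_idx` column refers to.
#' @return Filtered feature table with attribute `drop_report`
#'   (`no_ms1_id`, `ms2_too_small`, `kept` counts).
#' @export
filter_candidates <- function(features, run) {
  has_id <- vapply(features$formula_candidates, function(fc)
    !is.null(fc) && nrow(fc) > 0, logical(1))
  has_ms2 <- vapply(features$ms2_idx, function(ix) {
    if (length(ix) == 0) return(FALSE)
    any(vapply(ix, function(i) length(run$spectra[[i]]$mz) >= 4, logical(1)))
  }, logical(1))
  report <- c(no_ms1_id = sum(!has_id),
              ms2_too_small = sum(has_id & !has_ms2),
              kept = sum(has_id & has_ms2))
  out <- features[has_id & has_ms2, , drop = FALSE]
  attr(out, "drop_report") <- report
  out
}

#' Extract transitions from an annotated fragmentation tree
#'
#' Takes the `n` highest-intensity annotated fragments (precursor node
#' excluded), requiring a relative intensity of at least
#' `min_rel_intensity` of the strongest fragment. Ties in intensity are
#' broken by lower m/z. Library intensities are max-normalized.
#'
#' @param tree A [build_tree()] result.
#' @param n Maximum number of transitions.
#' @param min_rel_intensity Relative intensity floor in (0, 1).
#' @return Data frame `fragment_mz`, `library_intensity`,
#'   `fragment_formula`, sorted by decreasing intensity.
#' @export
extract_transitions <- function(tree, n = 3, min_rel_intensity = 0.05) {
  stopifnot(inherits(tree, "frag_tree"))
  nd <- tree$nodes[-1, , drop = FALSE]   # drop precursor/root node
  nd <- nd[!is.na(nd$intensity), , drop = FALSE]
  if (nrow(nd) == 0)
    return(data.frame(fragment_mz = numeric(0), library_intensity = numeric(0),
                      fragment_formula = character(0)))
  rel <- nd$intensity / max(nd$intensity)
  nd <- nd[rel >= min_rel_intensity, , drop = FALSE]
  nd <- nd[order(-nd$intensity, nd$mz), , drop = FALSE]
  nd <- nd[seq_len(min(n, nrow(nd))), , drop = FALSE]
  data.frame(fragment_mz = nd$mz,
             library_intensity = nd$intensity / max(nd$intensity),
             fragment_formula = nd$formula, stringsAsFactors = FALSE)
}

#' Resolve multiple candidates for one compound/adduct
#'
#' The same compound and adduct may yield several candidate features (e.g.
#' column saturation, isobars). The candidate with the highest corrected
#' precursor intensity is retained; ties go to the earlier retention time.
#'
#' @param candidates List of candidate descriptors, each with elements
#'   `precursor_intensity` and `rt`.
#' @return The retained candidate.
#' @export
resolve_ambiguity <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  int <- vapply(candidates, `[[`, numeric(1), "precursor_intensity")
  rt <- vapply(candidates, `[[`, numeric(1), "rt")
  candidates[[order(-int, rt)[1]]]
}

#' Merge assay libraries from multiple collision-energy ranges
#'
#' Per compound/adduct: an assay present in only one library is taken as-is;
#' one present in several is taken from the library giving more transitions
#' (ties: higher precursor intensity recorded at build time, then first
#' library). A coverage report is attached as attribute `"merge_report"`.
#'
#' @param libraries List of libraries (each a list of transition groups).
#' @param strategy Only `"more_transitions"` is implemented.
#' @return Merged library (list of transition groups).
#' @export
merge_collision_energies <- function(libraries, strategy = "more_transitions") {
  stopifnot(strategy == "more_transitions")
  pool <- list()
  origin <- integer(0)
  for (li in seq_along(libraries)) for (g in libraries[[li]]) {
    key <- paste(g$compound_name, g$adduct)
    if (!key %in% names(pool)) {
      pool[[key]] <- g
      origin[key] <- li
    } else {
      old <- pool[[key]]
      n_new <- nrow(g$transitions); n_old <- nrow(old$transitions)
      pi_new <- attr(g, "precursor_intensity") %||% 0
      pi_old <- attr(old, "precursor_intensity") %||% 0
      if (n_new > n_old || (n_new == n_old && pi_new > pi_old)) {
        pool[[key]] <- g
        origin[key] <- li
      }
    }
  }
  out <- unname(pool)
  attr(out, "merge_report") <- table(factor(origin, levels = seq_along(libraries)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a target assay library from DDA runs
#'
#' Runs the full candidate-identification and library-construction chain:
#' feature detection, isotope-trace filtering, adduct grouping,
#' accurate-mass search, precursor correction, MS2 mapping, the 4-peak MS2
#' filter, fragmentation trees, transition extraction, ambiguity resolution
#' and (for multiple runs, e.g. collision-energy ranges) per-compound
#' merging.
#'
#' @param dda_runs A single DDA run or list of runs (one per
#'   collision-energy range).
#' @param compound_db Data frame `name`, `formula`, optional `rt_sec`.
#' @param params Named list overriding defaults: `ppm_tol_trace`,
#'   `min_scans`, `min_traces`, `rt_tol_adduct`, `ppm_tol_search`,
#'   `precursor_snap_tol`, `ppm_tol_map`, `ppm_tol_tree`, `n_transitions`,
#'   `min_rel_intensity`, `min_annotated`.
#' @return List with `library` (transition groups), `trees` (fragmentation
#'   trees keyed by group_id) and `report` (drop counts and coverage at
#'   1/2/3-transition thresholds relative to the compound database).
#' @export
build_library <- function(dda_runs, compound_db, params = list()) {
  p <- utils::modifyList(list(
    ppm_tol_trace = 10, min_scans = 5, min_traces = 2, rt_tol_adduct = 10,
    ppm_tol_search = 5, precursor_snap_tol = 0.05, ppm_tol_map = 10,
    ppm_tol_tree = 10, n_transitions = 3, min_rel_intensity = 0.05,
    min_annotated = 1), params)
  if (inherits(dda_runs, "ms_run")) dda_runs <- list(dda_runs)
  per_run <- lapply(dda_runs, function(run) {
    ft <- detect_features(run, p$ppm_tol_trace, p$min_scans)
    if (nrow(ft) == 0)
      return(list(library = list(), trees = list(),
                  drop = c(no_ms1_id = 0, ms2_too_small = 0, kept = 0)))
    ft <- filter_by_isotope_traces(ft, p$min_traces)
    ft <- group_adducts(ft, p$rt_tol_adduct, p$ppm_tol_trace)
    ft <- accurate_mass_search(ft, compound_db, p$ppm_tol_search)
    run <- correct_precursors(run, p$precursor_snap_tol)
    ft <- map_ms2_to_features(ft, run, p$ppm_tol_map)
    ft <- filter_candidates(ft, run)
    drop <- attr(ft, "drop_report")
    cand <- list()
    for (i in seq_len(nrow(ft))) {
      best <- ft$formula_candidates[[i]][1, ]
      ms2_i <- ft$ms2_idx[[i]]
      ms2_i <- ms2_i[vapply(ms2_i, function(k)
        length(run$spectra[[k]]$mz) >= 4, logical(1))]
      pint <- vapply(ms2_i, function(k) {
        v <- run$spectra[[k]]$precursor_intensity
        if (is.na(v)) 0 else v
      }, numeric(1))
      sp <- run$spectra[[ms2_i[which.max(pint)]]]
      key <- paste(best$name, if (is.na(ft$adduct[i])) "[M+H]+" else ft$adduct[i])
      cand[[key]] <- c(cand[[key]], list(list(
        feature_row = i, spectrum = sp, precursor_intensity = max(pint),
        rt = ft$rt_apex[i], name = best$name, formula = best$formula,
        adduct = if (is.na(ft$adduct[i])) "[M+H]+" else ft$adduct[i],
        mz = ft$mz[i])))
    }
    lib <- list(); trees <- list()
    for (key in names(cand)) {
      ch <- resolve_ambiguity(cand[[key]])
      tree <- build_tree(ch$formula, ch$spectrum, p$ppm_tol_tree,
                         min_annotated = p$min_annotated)
      if (is.null(tree)) next
      tr <- extract_transitions(tree, p$n_transitions, p$min_rel_intensity)
      if (nrow(tr) == 0) next
      gid <- paste0(ch$name, "_", ch$adduct)
      g <- transition_group(gid, ch$name, ch$formula, ch$adduct,
                            adduct_mz(monoisotopic_mass(ch$formula), ch$adduct),
                            ch$rt, tr)
      attr(g, "precursor_intensity") <- ch$precursor_intensity
      lib[[gid]] <- g
      trees[[gid]] <- tree
    }
    list(library = lib, trees = trees, drop = drop)
  })
  if (length(per_run) == 1) {
    lib <- per_run[[1]]$library
    trees <- per_run[[1]]$trees
  } else {
    lib <- merge_collision_energies(lapply(per_run, `[[`, "library"))
    names(lib) <- vapply(lib, `[[`, character(1), "group_id")
    trees <- list()
    for (pr in per_run) trees[names(pr$trees)] <- pr$trees
    trees <- trees[names(lib)]
  }
  drop <- Reduce(`+`, lapply(per_run, `[[`, "drop"))
  n_db <- nrow(compound_db)
  ntr <- vapply(lib, function(g) nrow(g$transitions), integer(1))
  cov <- vapply(1:3, function(k) {
    cmp <- unique(vapply(lib[ntr >= k], `[[`, character(1), "compound_name"))
    length(cmp) / max(n_db, 1)
  }, numeric(1))
  report <- list(drop_counts = drop,
                 coverage = c(`1_transition` = cov[1], `2_transitions` = cov[2],
                              `3_transitions` = cov[3]))
  list(library = unname(lib), trees = trees, report = report)
}
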