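# Evaluation harness: FDR calibration against ground truth, precision-
# recall, dilution-series quantification metrics, limit of detection and
# the transition-count ambiguity simulation.

rbind_list <- function(l) {
  if (length(l) == 0) return(NULL)
  do.call(rbind, c(l, list(make.row.names = FALSE)))
}

#' Confusion counts at a q-value threshold
#'
#' A scored rank-1 target detection at `q_value <= q_threshold` is a true
#' positive if a ground-truth entry matches its (compound, adduct, run) and
#' the retention-time deviation is at most `rt_tol` (default 5 s); otherwise
#' it is a false positive. False negatives are unmatched truth entries.
#'
#' @param results Scored peak-group table (targets; decoys are ignored).
#' @param ground_truth Data frame `compound`, `adduct`, `run_id`, `rt_sec`.
#' @param rt_tol RT tolerance in seconds.
#' @param q_threshold q-value threshold.
#' @return Named vector `TP`, `FP`, `FN`.
#' @export
confusion_at_threshold <- function(results, ground_truth, rt_tol = 5,
                                   q_threshold = 0.05) {
  hits <- filter_results(results[!results$is_decoy, , drop = FALSE],
                         q_threshold, best_rank_only = TRUE)
  truth_key <- paste(ground_truth$compound, ground_truth$adduct,
                     ground_truth$run_id)
  matched_truth <- rep(FALSE, nrow(ground_truth))
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(hits))) {
    key <- paste(hits$compound_name[i], hits$adduct[i], hits$run_id[i])
    j <- which(truth_key == key &
                 abs(ground_truth$rt_sec - hits$rt_apex[i]) <= rt_tol)
    if (length(j) > 0) {
      tp <- tp + 1L
      matched_truth[j[1]] <- TRUE
    } else fp <- fp + 1L
  }
  c(TP = tp, FP = fp, FN = sum(!matched_truth))
}

#' Empirical false-discovery rate from confusion counts
#'
#' FDR = FP / (FP + TP).
#'
#' @param TP,FP True and false positive counts.
#' @return The realized false-discovery proportion.
#' @export
empirical_fdr <- function(TP, FP) {
  if (TP + FP == 0) stop("empirical FDR undefined: no positive calls")
  FP / (FP + TP)
}

#' FDR calibration curve and precision-recall
#'
#' Confusion counts at each estimated-FDR threshold on a grid (default 60
#' log-spaced points between 0.1% and 30%), with the precision-recall AUC
#' by the trapezoid rule (anchored at recall 0, precision 1).
#'
#' @param results Scored table.
#' @param ground_truth Truth table (see [confusion_at_threshold()]).
#' @param thresholds Estimated-FDR grid.
#' @param rt_tol RT tolerance (seconds).
#' @return Data frame `estimated_fdr`, `TP`, `FP`, `FN`, `true_fdr`,
#'   `precision`, `recall`; attribute `pr_auc`.
#' @export
calibration_curve <- function(results, ground_truth,
                              thresholds = exp(seq(log(0.001), log(0.30),
                                                   length.out = 60)),
                              rt_tol = 5) {
  rows <- lapply(thresholds, function(thr) {
    cf <- confusion_at_threshold(results, ground_truth, rt_tol, thr)
    data.frame(estimated_fdr = thr, TP = cf["TP"], FP = cf["FP"], FN = cf["FN"],
               true_fdr = if (cf["TP"] + cf["FP"] > 0)
                 empirical_fdr(cf["TP"], cf["FP"]) else NA_real_,
               precision = if (cf["TP"] + cf["FP"] > 0)
                 cf["TP"] / (cf["TP"] + cf["FP"]) else NA_real_,
               recall = if (cf["TP"] + cf["FN"] > 0)
                 cf["TP"] / (cf["TP"] + cf["FN"]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$precision) & !is.na(out$recall)
  pr <- out[ok, c("recall", "precision")]
  pr <- pr[order(pr$recall), , drop = FALSE]
  pr <- rbind(data.frame(recall = 0, precision = 1), pr)
  auc <- if (nrow(pr) >= 2)
    sum(diff(pr$recall) * (pr$precision[-nrow(pr)] + pr$precision[-1]) / 2)
  else NA_real_
  attr(out, "pr_auc") <- auc
  out
}

#' Dilution-series quantification metrics
#'
#' Per compound/adduct: mean areas per dilution step (replicate-averaged,
#' restricted to steps detected in all replicates), intensities
#' max-normalized by the highest-concentration step, ratios between
#' consecutive detected steps, coefficient of variation (sd/mean of the
#' non-normalized areas across replicates) per step, and the last detected
#' step.
#'
#' @param results Scored table filtered to accepted detections (e.g.
#'   `filter_results(x, 0.05)`), with `total_area` as the quantity.
#' @param run_design Data frame `run_id`, `dilution_step`, `replicate`
#'   (e.g. unique rows of the simulator truth).
#' @param n_replicates Replicates required per step (triplicate presence).
#' @return List with `per_step` (compound, adduct, step, mean_area,
#'   norm_intensity, cv, n_reps), `ratios` (compound, adduct, step_from,
#'   ratio of consecutive detected steps) and `last_step` per compound.
#' @export
quantify_dilution_series <- function(results, run_design, n_replicates = 3) {
  res <- results[!results$is_decoy, , drop = FALSE]
  m <- match(res$run_id, run_design$run_id)
  res$dilution_step <- run_design$dilution_step[m]
  res$replicate <- run_design$replicate[m]
  res <- res[!is.na(res$dilution_step), , drop = FALSE]
  per_step <- list(); ratios <- list(); last_step <- list()
  for (key in unique(paste(res$compound_name, res$adduct))) {
    sub <- res[paste(res$compound_name, res$adduct) == key, , drop = FALSE]
    steps <- sort(unique(sub$dilution_step))
    rows <- lapply(steps, function(st) {
      a <- sub$total_area[sub$dilution_step == st]
      data.frame(compound = sub$compound_name[1], adduct = sub$adduct[1],
                 step = st, mean_area = mean(a),
                 cv = if (length(a) >= 2) stats::sd(a) / mean(a) else NA_real_,
                 n_reps = length(a), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[tab$n_reps >= n_replicates, , drop = FALSE]
    if (nrow(tab) == 0) next
    tab$norm_intensity <- tab$mean_area / tab$mean_area[which.min(tab$step)]
    per_step[[key]] <- tab
    if (nrow(tab) >= 2) {
      consec <- which(diff(tab$step) == 1)
      if (length(consec) > 0)
        ratios[[key]] <- data.frame(
          compound = tab$compound[1], adduct = tab$adduct[1],
          step_from = tab$step[consec],
          ratio = tab$mean_area[consec] / tab$mean_area[consec + 1],
          stringsAsFactors = FALSE)
    }
    last_step[[key]] <- data.frame(compound = tab$compound[1],
                                   adduct = tab$adduct[1],
                                   last_step = max(tab$step),
                                   stringsAsFactors = FALSE)
  }
  list(per_step = rbind_list(per_step), ratios = rbind_list(ratios),
       last_step = rbind_list(last_step))
}

#' Limit of detection along the dilution series
#'
#' Uses the unfiltered results: per compound/adduct, the deepest dilution
#' step whose median peak-group signal-to-noise (the `sn` sub-score,
#' log scale) still reaches `sn_threshold`.
#'
#' @param results_unfiltered Scored table including sub-scores, rank-1 rows
#'   are used.
#' @param run_design Data frame `run_id`, `dilution_step`.
#' @param sn_threshold S/N threshold (linear scale, default 10).
#' @return Data frame `compound`, `adduct`, `lod_step` (`NA` when no step
#'   reaches the threshold).
#' @export
limit_of_detection <- function(results_unfiltered, run_design, sn_threshold = 10) {
  res <- results_unfiltered[!results_unfiltered$is_decoy &
                              results_unfiltered$rank == 1, , drop = FALSE]
  res$dilution_step <- run_design$dilution_step[match(res$run_id, run_design$run_id)]
  res <- res[!is.na(res$dilution_step), , drop = FALSE]
  out <- list()
  for (key in unique(paste(res$compound_name, res$adduct))) {
    sub <- res[paste(res$compound_name, res$adduct) == key, , drop = FALSE]
    sn_by_step <- tapply(exp(sub$sn), sub$dilution_step, stats::median)
    ok <- as.integer(names(sn_by_step))[sn_by_step >= sn_threshold]
    out[[key]] <- data.frame(compound = sub$compound_name[1],
                             adduct = sub$adduct[1],
                             lod_step = if (length(ok) > 0) max(ok) else NA_integer_,
                             stringsAsFactors = FALSE)
  }
  rbind_list(out)
}

#' Transition-count ambiguity simulation
#'
#' Simulates MS methods of varying precursor/fragment window width and
#' transition count: a library compound is uniquely identified at a setting
#' iff no background compound falls within the precursor window and matches
#' at least `k` of the compound's top-`k` fragments within the fragment
#' window. `k = 0` corresponds to MS1-only identification (precursor window
#' alone).
#'
#' @param library,background_library Lists of transition groups (the
#'   background is e.g. a large metabolome library).
#' @param precursor_tol_list,fragment_tol_list Window half-widths (Th).
#' @param n_transitions_list Transition counts `k` to test.
#' @return Data frame `precursor_tol`, `fragment_tol`, `n_transitions`,
#'   `n_unique`.
#' @export
simulate_unique_identifications <- function(library, background_library,
                                            precursor_tol_list,
                                            fragment_tol_list,
                                            n_transitions_list) {
  lib_prec <- vapply(library, `[[`, numeric(1), "precursor_mz")
  bg_prec <- vapply(background_library, `[[`, numeric(1), "precursor_mz")
  lib_frag <- lapply(library, function(g)
    g$transitions$fragment_mz[order(-g$transitions$library_intensity)])
  bg_frag <- lapply(background_library, function(g) g$transitions$fragment_mz)
  rows <- list()
  for (pt in precursor_tol_list) for (ft in fragment_tol_list)
    for (k in n_transitions_list) {
      uniq <- vapply(seq_along(library), function(i) {
        near <- which(abs(bg_prec - lib_prec[i]) <= pt)
        if (length(near) == 0) return(TRUE)
        if (k == 0) return(FALSE)
        top <- lib_frag[[i]][seq_len(min(k, length(lib_frag[[i]])))]
        conflict <- vapply(near, function(b) {
          matches <- vapply(top, function(m)
            any(abs(m - bg_frag[[b]]) <= ft), logical(1))
          sum(matches) >= length(top)
        }, logical(1))
        !any(conflict)
      }, logical(1))
      rows[[length(rows) + 1]] <- data.frame(
        precursor_tol = pt, fragment_tol = ft, n_transitions = k,
        n_unique = sum(uniq))
    }
  do.call(rbind, rows)
}
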