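# End-to-end study harnesses: complete simulate -> assay -> decoy ->
# extract -> score -> evaluate chains at desk scale. These are the entry
# points the evaluation of FDR calibration and quantification accuracy is
# built on.

#' Run one FDR-calibration study
#'
#' Simulates a single DIA run containing `n_true` injected compounds, adds
#' `n_absent` syntactically valid target assays for compounds never injected
#' (their traces contain only noise), generates one decoy per target by tree
#' re-rooting with CH2 fallback, extracts and scores all peak groups, learns
#' the discriminant and estimates q-values. The realized false-discovery
#' proportion among accepted targets is computed against the simulator's
#' ground truth with the 5 s retention-time rule.
#'
#' @param seed Integer seed; controls compounds, runs, decoys and learning.
#' @param n_true Number of injected compounds.
#' @param n_absent Number of absent target assays.
#' @param q_threshold Acceptance threshold for the realized-FDP readout.
#' @param gradient_length,ms1_interval,noise_peaks Simulation scale knobs.
#' @return List: `results` (scored table), `truth`, `hits` (accepted rank-1
#'   targets), `n_hits`, `n_false`, `fdp` (realized false-discovery
#'   proportion at `q_threshold`), `pr_auc`, `pi0`.
#' @export
run_calibration_study <- function(seed = 1, n_true = 60, n_absent = 60,
                                  q_threshold = 0.05, gradient_length = 360,
                                  ms1_interval = 1.8, noise_peaks = 2000) {
  set.seed(seed)
  compounds <- sim_compound_set(n_true, gradient_length = gradient_length,
                                n_fragments = 5)
  design <- sim_design(compounds, n_dilutions = 1, n_replicates = 1,
                       gradient_length = gradient_length,
                       ms1_interval = ms1_interval,
                       noise_peaks_per_spectrum = noise_peaks,
                       intensity_cv = 0.1, seed = seed)
  sim <- simulate_dia(design)
  targets <- design_assays(design, n = 3)
  absent <- make_absent_assays(design, n_absent, n = 3)
  trees <- c(attr(targets, "trees"), attr(absent, "trees"))
  all_targets <- c(unname(targets), unname(absent))
  dec <- generate_decoys(all_targets, seed = seed + 1, trees = trees)
  pg <- extract_peak_groups(sim$runs, dec$library)
  scored <- score_peak_groups(pg, seed = seed + 2)
  truth <- sim$truth[, c("compound", "adduct", "run_id", "rt_sec")]
  hits <- filter_results(scored[!scored$is_decoy, , drop = FALSE], q_threshold)
  truth_key <- paste(truth$compound, truth$adduct, truth$run_id)
  is_tp <- vapply(seq_len(nrow(hits)), function(i) {
    key <- paste(hits$compound_name[i], hits$adduct[i], hits$run_id[i])
    any(truth_key == key & abs(truth$rt_sec - hits$rt_apex[i]) <= 5)
  }, logical(1))
  cal <- calibration_curve(scored, truth)
  list(results = scored, truth = truth, hits = hits,
       n_hits = nrow(hits), n_false = sum(!is_tp),
       fdp = if (nrow(hits) > 0) mean(!is_tp) else NA_real_,
       pr_auc = attr(cal, "pr_auc"), calibration = cal,
       pi0 = attr(scored, "pi0"),
       decoy_report = dec$report)
}

#' Run one dilution-series quantification study
#'
#' Simulates the full dilution series (default: 10 steps, 4-fold,
#' triplicate — spanning more than five orders of magnitude), extracts and
#' scores against the design's target assays plus decoys, filters at the
#' q-value threshold and computes quantification metrics: consecutive-step
#' intensity ratios, replicate CVs and S/N-based limits of detection.
#'
#' @param seed Integer seed.
#' @param n_compounds Number of injected compounds.
#' @param n_dilutions,dilution_factor,n_replicates Dilution design.
#' @param intensity_cv Replicate lognormal CV.
#' @param q_threshold Acceptance threshold.
#' @param gradient_length,ms1_interval,noise_peaks Simulation scale knobs.
#' @return List: `results`, `quant` (see [quantify_dilution_series()]),
#'   `lod`, `truth`, `run_design`.
#' @export
run_quantification_study <- function(seed = 1, n_compounds = 12,
                                     n_dilutions = 10, dilution_factor = 4,
                                     n_replicates = 3, intensity_cv = 0.1,
                                     q_threshold = 0.05,
                                     gradient_length = 150,
                                     ms1_interval = 1.5, noise_peaks = 400) {
  set.seed(seed)
  compounds <- sim_compound_set(n_compounds, gradient_length = gradient_length,
                                n_fragments = 5)
  design <- sim_design(compounds, n_dilutions = n_dilutions,
                       dilution_factor = dilution_factor,
                       n_replicates = n_replicates,
                       gradient_length = gradient_length,
                       ms1_interval = ms1_interval,
                       intensity_cv = intensity_cv,
                       noise_peaks_per_spectrum = noise_peaks, seed = seed)
  sim <- simulate_dia(design)
  targets <- design_assays(design, n = 3)
  dec <- generate_decoys(unname(targets), seed = seed + 1,
                         trees = attr(targets, "trees"))
  pg <- extract_peak_groups(sim$runs, dec$library)
  # few assays but many runs: relax the group-count floor for learning
  scored <- score_peak_groups(pg, params = list(min_groups = 8), seed = seed + 2)
  run_design <- unique(sim$truth[, c("run_id", "dilution_step", "replicate")])
  accepted <- filter_results(scored, q_threshold)
  quant <- quantify_dilution_series(accepted, run_design, n_replicates)
  lod <- limit_of_detection(scored, run_design)
  list(results = scored, quant = quant, lod = lod, truth = sim$truth,
       run_design = run_design)
}
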