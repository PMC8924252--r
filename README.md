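# metaswath

Targeted analysis of DIA/SWATH metabolomics data with statistically
calibrated false-discovery rate control.

## The problem

Data-independent acquisition (DIA/SWATH) cycles through fixed precursor
isolation windows and records highly multiplexed MS2 spectra, giving
excellent quantitative coverage at the cost of spectrum purity. A targeted
analysis extracts fragment-level ion chromatograms (XICs) for every assay in
a transition library and must then decide which detected peak groups are
real. In the low signal-to-noise regime of DIA metabolomics this decision is
the hard part: without an error model, reported feature lists mix true
detections with chromatographic noise in unknown proportion.

`metaswath` implements a complete end-to-end workflow for this problem:

1. **Candidate identification** (DDA runs): mass-trace feature detection,
   isotope-trace filtering, adduct grouping (`[M+H]+`, `[M+Na]+`, `[M+K]+`),
   and accurate-mass search against a compound database.
2. **Library construction**: MS2 spectra are assigned to features, fragments
   are annotated with subformulas of the precursor via compositional
   fragmentation trees, and the *n* highest-intensity annotated fragments
   become the assay's transitions (default *n* = 3).
3. **Decoy generation**: one decoy per target by fragmentation-tree
   re-rooting — the tree's neutral-loss multiset is conserved exactly while
   the fragment masses are rearranged; decoy fragments that collide with
   target fragments are shifted by the CH2 mass (+14.01565 Da), and a CH2
   shift of all fragments serves as fallback when re-rooting is impossible.
   No decoy is generated on the MS1 level.
4. **Targeted extraction** (DIA runs): per-window XIC extraction, peak-group
   detection on the smoothed summed fragment trace, and a sub-score vector
   per peak group (co-elution shift, chromatogram shape correlation,
   library-intensity correlation, S/N, MS1 isotope correlation, MS1/MS2
   co-elution).
5. **Statistical validation**: semi-supervised learning of a linear
   discriminant (LDA) on the target/decoy sub-scores, d-scores standardized
   to the decoy null, per-target p-values from decoy exceedance, and
   q-values

   q(s) = min over s' <= s of [ pi0 · N_t · P_decoy(d >= s') / #{targets with d >= s'} ],

   with pi0 estimated by Storey's fixed-lambda rule on the decoy-null
   p-values. Filtering at q <= 0.05 then controls the FDR among reported
   peak groups.

A synthetic-data module simulates DDA and DIA acquisitions of known
compounds — Gaussian elution, isotope envelopes, SWATH cycles, ppm mass
jitter, dense exponential-intensity chemical noise, and a 4-fold, 10-step
dilution series in triplicate — so that every stage of the pipeline is
testable against ground truth, including assays for compounds that were
never injected (the empirical check that estimated q-values match the
realized false-discovery proportion).

## Worked example

```r
library(metaswath)

set.seed(7)
compounds <- sim_compound_set(20, gradient_length = 400)

# DDA run of clean reference standards -> target assay library
dda_design <- sim_design(compounds, n_dilutions = 1, n_replicates = 1,
                         gradient_length = 400, ms1_interval = 2,
                         noise_peaks_per_spectrum = 30, seed = 7)
dda <- simulate_dda(dda_design)
db <- data.frame(name    = sapply(compounds, `[[`, "name"),
                 formula = sapply(compounds, function(x) formula_to_string(x$formula)))
lib <- build_library(dda$run, db)
lib$report$coverage
#> 1_transition 2_transitions 3_transitions
#>            1             1             1

# re-rooted decoys; DIA run in a noisy matrix; extract and score
td <- generate_decoys(lib$library, seed = 7, trees = lib$trees)
dia_design <- sim_design(compounds, n_dilutions = 1, n_replicates = 1,
                         gradient_length = 400, ms1_interval = 2,
                         noise_peaks_per_spectrum = 2000, seed = 7)
dia <- simulate_dia(dia_design)
pg <- extract_peak_groups(dia$runs, td$library)
scored <- score_peak_groups(pg, params = list(min_groups = 15), seed = 7)
hits <- filter_results(scored, q_threshold = 0.05)
nrow(hits)
#> [1] 20
round(attr(scored, "weights"), 3)
#>  xcorr_coelution      xcorr_shape     library_corr               sn
#>           -0.056            0.870            0.360            0.063
#> ms1_isotope_corr    ms1_coelution
#>            0.323           -0.036
```

The full library is recovered (coverage 100% at three transitions) and all
20 injected compounds pass q <= 0.05. The `scored` table carries one row per
peak group with its sub-scores, d-score, p-value and q-value; the learned
discriminant leans on chromatogram shape, library-intensity correlation and
the MS1 isotope pattern, with co-elution shifts entering negatively (larger
shift, worse candidate).

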