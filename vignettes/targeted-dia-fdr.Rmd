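---
title: "Targeted DIA metabolomics with target-decoy FDR control: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted DIA metabolomics with target-decoy FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaswath)
```

This vignette explains the models and assumptions behind `metaswath`, the
tunable parameters that matter, what the synthetic-data generator does and
does not emulate, and the design choices made where the design was genuinely
open. The README shows the workflow itself; here we concentrate on *why* the
pieces look the way they do.

## The statistical core

The workflow is a target-decoy procedure. Every assay (compound + adduct +
transitions) in the library is probed in the DIA data; for each assay the
extraction stage reports candidate peak groups with a vector of sub-scores.
Because decoy assays are constructed so that their fragment coordinates
carry no true signal, their peak groups sample the score distribution of
chromatographic noise. The statistical machinery is then:

1. **Discriminant learning.** A linear discriminant is learned
   semi-supervisedly: starting from the single sub-score with the largest
   |AUC − 0.5| between targets and decoys, the current score ranks the peak
   groups; target assays with q ≤ 0.15 become positives, all decoy peak
   groups negatives; a two-class LDA with pooled covariance (ridge 10⁻⁶ of
   the mean diagonal for stability) is refit and the loop repeats (10
   iterations). This runs inside 3-fold cross-validation over assays, and
   the final weight vector is the fold average, unit-normalized. A linear
   model is a deliberate guard against overfitting the modest number of
   assays available in a typical experiment.
2. **d-scores.** The combined score is standardized so that rank-1 decoy
   peak groups have mean 0 and standard deviation 1. All downstream
   thresholds live on this decoy-null scale.
3. **Error estimation.** Per target, p = (1 + #{decoys ≥ s}) / (1 + N_d) —
   the add-one smoothing keeps reported p-values away from an impossible
   zero. The q-value at score s is the monotonized minimum over thresholds
   of pi0 · N_t · p(s') / #{targets ≥ s'}, with pi0 estimated by Storey's
   fixed-lambda rule (lambda = 0.5) on the target p-values and clipped to
   (0, 1]. A plain counting estimator (#decoys ≥ s / #targets ≥ s, pi0 = 1)
   is available as `pi0_method = "counting"` and is used in the learning
   loop, where only the ranking of thresholds matters.

The premise that makes any of this valid is *null exchangeability*: decoy
peak groups must behave like the peak groups of false targets. Two design
choices below (decoy tree topology, noise density) exist precisely to
protect that premise, and the package's headline test simulates assays for
compounds that were never injected and checks that the realized
false-discovery proportion at q ≤ 0.05 falls inside the 95% binomial band
around 0.05 over ten seeds.

## Fragmentation trees

Fragment annotation assigns each MS2 peak a subformula of the precursor
formula. The enumeration is exact: all element-wise subformulas whose
protonated mass ([fragment + H]⁺; fragments are treated as singly protonated
even-electron ions) lies within the ppm tolerance, filtered to
ring-double-bond equivalents ≥ −0.5, best match = smallest |ppm| with
lexicographic tie-break for determinism. Annotated fragments are connected
into a tree: each fragment attaches, in decreasing mass order, to the
already-placed superset-formula node minimizing the neutral-loss mass; the
precursor is the root, so the tree is always connected, and by construction
every edge satisfies parent = child + loss exactly.

This is a deliberately minimal tree builder. There is no scored
maximum-arborescence optimization, no isotope scoring, and no multi-ion-type
annotation; determinism is bounded by an atom-count cap (≤ 60 atoms) rather
than a wall-clock budget. For library construction and decoy generation this
is sufficient: transitions only need correct masses and a loss multiset, not
an optimal topology.

## Decoys by tree re-rooting

A decoy assay must present realistic but wrong fragment coordinates. The
generator conserves the target tree's neutral-loss multiset exactly: the
decoy root keeps the precursor formula, the loss entering a uniformly chosen
non-root node is drawn first (promoting that node's lineage — the
"re-rooting" draw), the remaining losses are drawn in seeded random order,
and each loss attaches to the **smallest** compatible node. Decoy fragment
masses are then the precursor mass minus cumulative losses along the new
tree.

Attaching to the smallest compatible node matters. The natural-looking
alternative — attach to the largest compatible node — degenerates: the root
is always compatible and always largest, so every decoy becomes a star whose
fragments cluster just below the precursor mass. Because extraction windows
are ppm-scaled, heavier decoy fragments sweep wider absolute m/z windows and
collect more noise than the (lighter, loss-accumulated) fragments of real
false targets; the decoy null then over-states the noise scores and the
estimated FDR becomes badly conservative. Smallest-node attachment extends
lineages instead, so decoy masses are cumulative loss sums with the same
mass distribution as real fragments — and the calibration property holds.

Two safeguards complete the scheme. Any decoy fragment within 0.01 Th of a
target fragment is shifted by the CH2 mass (+14.01565 Da), repeatedly if the
shifted mass collides again, so decoy and target transitions are always
disjoint. When re-rooting is impossible (single-node tree, no tree, or a
decoy too similar to its target — more than 80% of fragments within 0.01 Th)
the fallback shifts *all* target fragment masses by +14.01565 Da; a guard
refuses to apply the fallback to an existing decoy, since the shift must not
accumulate. The per-target method (rerooted / overlap-shifted / fallback) is
reported, not asserted: its mix depends on tree shapes. The precursor m/z is
never altered — on MS1 no decoy is generated — which means decoys of truly
present compounds inherit genuine MS1 signal; this is a known source of mild
conservatism in the estimated FDR.

## Targeted extraction and sub-scores

XICs are summed centroid intensities within ±25 ppm per scan, on the scan
grid of the assay's SWATH window (half-open [lower, upper) windows; a
boundary m/z belongs to the upper window), restricted to the library RT
± 60 s. MS1 traces cover the precursor and its first two isotopes. Peak
groups are picked on the Gaussian-smoothed (σ = 2 scans) summed MS2 trace:
local maxima, strongest first up to rank 5, boundaries at the nearest local
minimum or the 1% apex level. Sub-scores per peak group:

| score | definition | neutral value |
|---|---|---|
| `xcorr_coelution` | mean + sd of best-alignment shifts over transition pairs (±10 scans, mean-centered L2-normalized cross-correlation) | 0 with < 2 transitions |
| `xcorr_shape` | mean of maximal pairwise cross-correlations | 0 |
| `library_corr` | Pearson correlation of library intensities vs measured areas | 0 with < 2 transitions |
| `sn` | log median apex/noise; noise = 1.4826·MAD outside boundaries, floored at 1 count | — |
| `ms1_isotope_corr` | Pearson correlation of isotope-trace areas vs the formula's coarse isotope model | 0 without a formula |
| `ms1_coelution` | absolute best shift between precursor trace (interpolated onto the MS2 grid) and summed MS2 trace | 0 without MS1 |

The one-count noise floor in `sn` is physical (intensities are counts) and
keeps noise-free synthetic traces from producing unbounded ratios. These
scores are a documented, low-redundancy subset of what full targeted-DIA
engines compute; they are reimplementations, not ports, and the suite tests
their defining properties (a duplicated trace scores shift 0/shape 1, a
3-scan shift is recovered exactly, areas proportional to library intensities
give correlation 1).

## The synthetic-data generator

The generator defines the study conditions for every empirical claim the
package makes. It emulates: DDA runs (MS1 survey scans with M/M+1/M+2
isotope envelopes from a coarse model — 1.08% per carbon for M+1, oxygen and
sulfur terms for M+2 — plus precursor-selected MS2 spectra for every eluting
compound) and DIA runs (cycles of one MS1 scan followed by eight SWATH
scans tiling 100–900 Th); Gaussian chromatographic peaks (σ = 4 s);
ppm-scale mass jitter (Gaussian, 3 ppm sd — typical Q-TOF precision, and
compatible with the 10 ppm trace-linking tolerance); a 4-fold, 10-step
dilution series in triplicate spanning more than five orders of magnitude
(4⁹ ≈ 2.6·10⁵), with lognormal replicate noise at a stated CV; and dense
chemical noise — uniform-m/z, exponential-intensity spurious peaks, heavy
right tail. Compound formulas are pesticide-like small molecules (C8–C18
with N/O/S/Cl) whose fragment templates are built by cumulative neutral
losses, so every fragment is a true subformula of its precursor.

Noise density is a load-bearing parameter. Decoy and never-injected assays
only produce scoreable peak groups if their XIC windows catch noise; with
sparse noise the decoy null starves and no q-value can be estimated. The
calibration study therefore uses 2000 noise peaks per spectrum (about 2.4
peaks/Th over a SWATH window), the generic default is 400, and the DDA
library-construction examples use 30 (reference standards in clean solvent).

What the generator does **not** emulate: peak tailing and asymmetry, RT
drift between runs, ion suppression and matrix effects, correlated
(structured) chemical noise, profile-mode peak shapes, and charge states
beyond 1. Passing tests therefore demonstrate the *statistical machinery* —
calibration of q-values against ground truth under the stated noise model,
conservation laws of the decoy scheme, quantification linearity — not
robustness to every chromatographic pathology of real data.

## Numerical and scale choices

Study sizes were chosen so the whole suite runs comfortably on one CPU: the
calibration study uses one DIA run per seed (360 s gradient, 1.8 s cycles,
60 injected compounds, 60 absent assays, ten seeds), and the quantification
study uses 12 compounds over 30 runs (150 s gradient). Retention times are
seconds everywhere; atomic masses are CODATA monoisotopic values with the
electron mass included in adduct shifts; SWATH windows are half-open to make
boundary assignment unambiguous; trace linking uses the running
intensity-weighted centroid (linking to the last matched peak random-walks
under jitter and splits traces); ambiguous candidates resolve to the highest
corrected precursor intensity with earlier RT as tie-break; collision-energy
merging keeps the assay with more transitions. Degenerate inputs fail
loudly: profile-mode mzML, empty compound databases, runs without MS1 scans,
all-constant score matrices, and q-value estimation without decoys are all
errors, not warnings.

## Known limitations

Besides the generator's idealizations: the fragmentation-tree builder is a
stand-in for full Bayesian tree scoring and will mis-annotate when several
subformulas fall within tolerance of a peak; adduct grouping handles the
three common positive adducts and charge 1 only; there is no cross-run RT
alignment; the estimated FDR inherits mild conservatism from genuine MS1
signal under target-paired decoys; and the CH2 fallback produces decoys
whose fragment *spacing* mirrors the target exactly, which is why it is a
fallback and its usage fraction is reported.
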