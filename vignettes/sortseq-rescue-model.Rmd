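---
title: "Sort-seq variant scoring and the additive rescue model"
author: "sortrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sort-seq variant scoring and the additive rescue model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortrescue)
library(dplyr)
```

## The measurement and the estimator

sortrescue analyzes multiplexed surface-expression experiments in which a
pooled, barcoded saturation-mutagenesis library of a membrane protein is
immunostained without permeabilization, sorted by FACS into four
fluorescence bins, and sequenced per bin. A variant's phenotype is estimated
from how its barcodes distribute across bins.

The estimator chain is:

1. **Cell estimation.** A barcode's share of a bin's reads, times the
   number of cells sorted into that bin, estimates the cells of that
   genotype in the bin (`estimate_cells()`). Summing estimated cells over
   barcodes recovers each bin's sorted total exactly.
2. **Aggregation.** Barcodes coding for the same amino-acid change are
   combined (`aggregate_variants()`).
3. **Raw score.** The cell-count-weighted mean of the per-bin
   log10-transformed geometric-mean fluorescence values:
   $\mathrm{raw} = \sum_i c_i f_i \big/ \sum_i c_i$ over the four bins
   (`raw_score()`).
4. **Normalization.** Scores are rescaled so the wild-type genotype is 1
   and the median of premature stop codons before residue 300 is 0
   (`normalize_scores()`). Normalization is affine-equivariant: any
   positive affine transform of the fluorescence axis cancels.
5. **Replicate filtering and combination.** A replicate contributes to a
   variant only when that variant's estimated cells in the replicate reach
   `min_cells` (default 50); contributing replicates are averaged
   unweighted and their spread reported as the s.e.m.
   (`filter_and_combine()`).
6. **Categories.** The poor/moderate boundary is the 95th percentile of
   nonsense scores; the moderate/well boundary is the 5th percentile of
   synonymous wild-type scores (`expression_thresholds()`, `categorize()`).

Normalization is applied within each replicate, before combining, because
fluorescence units are not comparable across independent sorts; the anchors
are recomputed per replicate. The wild-type anchor is the unmutated
genotype's own barcodes, not the synonymous pool, which serves instead as
the upper category anchor.

Percentiles use linear interpolation between order statistics (R's default
type 7). Category boundaries are half-open: a score below the lower
threshold is poor, a score at or above the upper threshold is well; on a
continuous score the measure-zero ties make the convention immaterial, but
it is fixed for reproducibility.

## The rescue model

A second sort under a stabilizing condition — reduced temperature or a
pharmacological chaperone (a small molecule binding the folded state) —
measures the same library after a condition-level change in folding free
energy. The package's null model for that comparison is deliberately
minimal: a LOWESS curve of rescue score on control score
(`rescue_fit()`, fraction 0.3, 3 robustifying iterations, exact evaluation)
captures the expected, expression-level-dependent magnitude of rescue, and
per-variant residuals from that curve measure departures. Positions whose
residuals are systematically biased are found by a two-sided Mann-Whitney U
test of each position's residuals against the residuals at all other
positions, with Benjamini-Hochberg control at FDR 0.1
(`position_outlier_test()`).

Only variants with control score below 0.85 enter the test — variants
already at wild-type-like expression have no room to be rescued and only
dilute the comparison. The restriction applies to the position's own
variants *and* to the comparison pool, so both sides of the test see the
same population.

Tie handling in the U statistic uses midranks with a tie-corrected variance
and a continuity correction in the normal approximation; when both samples
have at most eight observations and no ties the p value is exact. The
per-variant rescue-magnitude call (`rescue_magnitude_calls()`) flags a
variant as significantly rescued when the rescue gain exceeds 1.96 times
the rescue score's s.e.m., i.e. the control score falls below the rescue
score's 95% confidence interval; a per-variant Normal interval was chosen
because the score is a mean over replicates and no better-resolved interval
is available at the variant level.

## The synthetic generator and what it emulates

`sim_config()` / `simulate_experiment()` generate complete sort-seq
experiments with known ground truth, so every stage above can be validated
by parameter recovery rather than against opaque fixtures.

The physical core is two-state folding: a variant with total folding free
energy $\Delta G$ folds with probability
$p = 1/(1 + e^{\Delta G / RT})$ (`folded_fraction()`, RT = 0.616 kcal/mol
at 37 °C), and its expected log10 surface fluorescence interpolates between
a null background and a fully-expressed level in linear fluorescence space
(`expected_fluor()`). Free energies combine additively:
$\Delta G = \Delta G_{wt} + \Delta\Delta G_{var} + \Delta\Delta G_{rescue}$,
with the rescue term applied only in the rescue condition and only at
rescuable positions. Planted non-rescuable positions emulate binding-site
or post-translational-modification residues whose defect is not a folding
defect; planted extra-rescue positions receive additional stabilization.
Nonsense variants bypass folding entirely and are assigned zero folded
fraction.

Key defaults, chosen once as the generator's study conditions:

| parameter | default | rationale |
|---|---|---|
| `dg_wt` | −2 kcal/mol | marginal stability typical of human proteins |
| `RT` | 0.616 kcal/mol | 37 °C |
| `ddg_rescue` | −3 kcal/mol | a few kcal/mol of binding stabilization |
| `ddg_mix_w` | 0.5 | roughly half of missense variants are near-neutral |
| neutral component | N(0, 0.3²) | small perturbations around zero |
| destabilizing component | Gamma(25, scale 0.2): 5 ± 1 kcal/mol | see below |
| `fluor_max`, `fluor_bg` | 4, 2 (log10) | a two-decade FACS staining range |
| `sigma_cell` | 0.3 log10 units | typical per-cell spread |
| `barcodes_per_variant` | 1 + Pois(4) | median 5 barcodes per variant |
| `n_bins` | 4 | four-way sort |
| `n_replicates` | 4 | replicate structure of a full experiment |

The destabilizing component deserves explanation, because it is a design
decision rather than an empirical fit. The score histogram of a real
saturation library is bimodal with the poorly-expressed peak *at* the
nonsense level: a large class of missense variants is effectively unfolded
at 37 °C, which under the two-state model means
$\Delta\Delta G_{var}$ of roughly 4 kcal/mol or more. At the same time, the
generator exists to validate the rescue statistics by planted-truth
recovery, and a planted effect is only detectable if destabilized variants
sit in the assay's informative window — control expression near zero but
rescue landing on the steep part of the sigmoid, where withheld or extra
stabilization changes the outcome. With
$\Delta G_{wt} = -2$ and $\Delta\Delta G_{rescue} = -3$, that window is
$\Delta\Delta G_{var} \approx 3.7$–$5.5$ kcal/mol. The default
Gamma(shape 25, scale 0.2) places the destabilizing mass at
5 ± 1 kcal/mol: the control histogram is bimodal with a poor peak at 0, and
rescue-outlier positions planted in either direction produce residual
shifts large enough to recover. A long-tailed alternative (many variants
beyond 7 kcal/mol) reproduces the histogram equally well but makes
*neither* direction detectable — the pool at low control expression is then
itself unrescuable, which collapses the contrast the outlier test relies
on. This is a real property of the method, not of the simulator: on real
data, positions can only be flagged relative to how the bulk of comparably
expressed variants responds.

The planted extra-rescue magnitude used in the validation scenarios,
−9 kcal/mol on top of the −3 baseline, corresponds to a chaperone
contributing its full binding free energy (on the order of −12 kcal/mol for
a high-affinity small molecule) at those positions.

Sampling follows the experiment: cells are drawn multinomially across
barcodes, each cell's log10 fluorescence is Normal around its genotype
mean, gates are placed at the quartiles of the realized fluorescence
distribution (mirroring sorts designed to fill bins evenly), and reads are
drawn multinomially over each bin's cell composition at the configured
depth. Long reads for barcode-variant association get per-read error-rate
estimates and a configurable fraction of miscalled variants, so the
quality, consensus and support filters of `build_barcode_map()` have
realistic work to do. All outputs are pure functions of (config, seed);
sub-streams per stage, replicate and condition are derived from the seed by
fixed offsets.

**What the generator does not emulate:** PCR amplification bias and
duplicate reads, barcode abundance skew from cloning bottlenecks, FACS
spillover, doublets and sorting impurity, day-to-day drift between
replicates (replicates differ only by sampling noise, so simulated
replicate correlations are higher than real ones), epistasis between the
barcode and the coding sequence, and any non-folding biology beyond the
planted non-rescuable positions (trafficking signals, glycosylation motif
context, signaling). Passing parameter-recovery tests therefore
demonstrates the estimator and statistics are correct under the stated
model, not that the model captures every feature of real libraries.

## Numerical choices

- **LOWESS** is Cleveland's algorithm (`stats::lowess`), the same family
  the field's analysis stacks use: span `fraction` of the points (window
  size truncated, `floor(f*n)`), tricube weights, bisquare robustifying
  iterations, `delta = 0` for exact evaluation at every point. Tied x
  values receive identical fitted values, and fits are returned in input
  order.
- **Degenerate inputs.** A bin with no cells is flagged, not an error; a
  variant with no estimated cells scores NA; a bin with sorted cells but no
  reads is an inconsistency and errors. Anchor degeneracy (wild type equal
  to the nonsense median) errors rather than producing unbounded scores.
- **Consensus** is strict: any disagreement among a barcode's reads marks
  it conflicted and drops it. Support rules follow the long-read filters: a
  single read is trusted only when its variant has two or more nucleotide
  changes, since a lone single-nucleotide call is indistinguishable from a
  sequencing miscall.
- **Ligand distances** are heavy-atom minima over all residue-ligand atom
  pairs (first model, alternate location A), the stricter of the common
  conventions; a Cα-based distance is a coarser upper bound.
- **Clinical classes** from multiple user lists resolve by a fixed
  precedence (pathogenic > likely_pathogenic > NDI > NSIAD > VUS >
  likely_benign > benign > gnomAD) so a variant appearing in several lists
  lands in its most clinically committed class.

## Problem sizes used by the test-suite and acceptance script

Validation runs use a 60-residue protein (about 1,260 variants and 6,300
barcodes), 5×10⁵ cells and 2×10⁶ reads per sort, four replicates per
condition for recovery checks, and two replicates at 2×10⁵ cells for the
repeated-seed null calibration — sizes at which every property of interest
(anchor recovery, Spearman recovery of the true folded fraction above 0.9,
planted-outlier recall in both directions, null false-flag rate at the FDR
level) is already stable across seeds.

## Known limitations

The rescue null curve conflates all sources of expression-level-dependent
response; it cannot separate a position-specific folding effect from a
position-specific trafficking effect, only flag the departure. The
high-confidence rule (cells per replicate and a minimum number of
replicates) is a heuristic, not an error model; no shrinkage or dispersion
modeling is applied, matching the estimator it implements. The Mann-Whitney
normal approximation is used whenever either sample exceeds eight
observations; for the position test this is essentially always, and exact
small-sample behavior matters only at sparsely covered positions.
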