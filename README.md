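# sortrescue

Analysis of multiplexed surface-expression (sort-seq / FACS-seq)
experiments on membrane-protein variant libraries, with a focus on
pharmacological-chaperone and temperature rescue. The package is for groups
running deep mutational scans of receptors or transporters who need to (i)
turn binned barcode counts into anchored per-variant expression scores, and
(ii) ask, position by position, which residues respond more or less to a
stabilizing condition than their expression level predicts — the signature
of drug-binding sites and of non-folding defects such as glycosylation
sites.

## What it computes

**Surface-expression scores.** With estimated cells $c_i$ of a genotype in
bin $i$ and per-bin log10 geometric-mean fluorescence $f_i$:

$$\mathrm{raw} = \frac{\sum_{i=1}^{4} c_i\, f_i}{\sum_{i=1}^{4} c_i},
\qquad
\mathrm{score} = \frac{\mathrm{raw} - \mathrm{median}(\mathrm{raw}_{stop})}
                      {\mathrm{raw}_{WT} - \mathrm{median}(\mathrm{raw}_{stop})}$$

so the wild type scores 1 and the median premature stop (before residue
300) scores 0. Replicates contribute only where a variant's estimated
cells reach 50, and variants are categorized poor / moderate / well
against the 95th percentile of nonsense scores and the 5th percentile of
synonymous scores.

**Rescue statistics.** A LOWESS curve (span 0.3, 3 robustifying passes) of
rescue score on control score is the null expectation for rescue at each
expression level; per-variant residuals from it are compared per position
against all other positions (two-sided Mann–Whitney U, restricted to
control scores < 0.85), with Benjamini–Hochberg control at FDR 0.1.
Per-variant rescue is called significant when the gain exceeds 1.96 × the
rescue score's s.e.m.

**Synthetic experiments with known truth.** A generator built on two-state
folding — folded fraction $1/(1+e^{\Delta G/RT})$ with additive
$\Delta G_{wt} + \Delta\Delta G_{var} + \Delta\Delta G_{rescue}$ — produces
complete sort-seq experiments (barcode maps, long reads, four-bin sorts,
replicates) so every stage is validated by parameter recovery. Planted
non-rescuable and extra-rescue positions make the outlier statistics
testable against ground truth.

Annotation helpers cover topology regions, clinical-class joins, predictor
AUROC (rank-based, ties at one half), per-position hydrophobicity
preference (Spearman against the Kyte–Doolittle scale) and minimum
heavy-atom ligand distances from a PDB structure.

## Worked example

Simulate a 60-residue receptor library with three planted non-rescuable
positions, score it, and run the rescue-outlier analysis:

```r
library(sortrescue)
library(dplyr)

cfg <- sim_config(L = 60, nonrescuable_positions = c(10, 25, 40), seed = 42)
ex <- simulate_experiment(cfg)
scores <- score_experiment(ex$counts, ex$bins, ex$library$barcode_map)

attr(scores, "thresholds")
#> # A tibble: 2 × 3
#>   condition    t_low t_high
#>   <chr>        <dbl>  <dbl>
#> 1 control   6.78e- 3  0.994
#> 2 rescue    9.84e-17  0.947

fit <- rescue_fit(filter(scores, condition == "control"),
                  filter(scores, condition == "rescue"))
fit
#> <rescue_fit>
#>   1253 paired variants; LOWESS fraction 0.30, 3 robust iterations
#>   mean residual 0.0001, residual s.d. 0.1060

filter(position_outlier_test(fit), outlier)
#> # A tibble: 3 × 8
#>   position n_variants mean_residual statistic  p.value q.value direction outlier
#>      <int>      <int>         <dbl>     <dbl>    <dbl>   <dbl> <chr>     <lgl>
#> 1       10         11        -0.379       346  3.28e-7 9.84e-6 less      TRUE
#> 2       25         11        -0.402       972  5.04e-5 1.01e-3 less      TRUE
#> 3       40         12        -0.632       410  1.32e-7 7.93e-6 less      TRUE
```

The three flagged positions are exactly the planted ones: their variants
are rescued less than variants of comparable control expression elsewhere
(`mean_residual` ≈ −0.4 to −0.6 score units below the LOWESS null), the
way a drug-binding-site mutation escapes a pharmacological chaperone.
`tidy(fit)` returns the per-variant residual table, `glance(fit)` the fit
summary, and `autoplot(fit)` the control-vs-rescue scatter with the null
curve. A full pipeline run (simulate → map barcodes → score → rescue →
annotate, with TSV/JSON artifacts and a manifest) is
`run_pipeline(run_config(), out_dir)`; a thin CLI wrapper lives at
`inst/scripts/sortrescue-cli.R`.

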