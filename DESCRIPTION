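Package: sortrescue
Title: Sort-Seq Variant Scoring and Pharmacological Chaperone Rescue Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of multiplexed surface-expression (sort-seq / FACS-seq)
    experiments on membrane-protein variant libraries. Provides a synthetic
    sort-seq generator built on a two-state folding model with additive
    free-energy rescue by a pharmacological chaperone, barcode-variant
    consensus mapping with long-read support filters, bin-weighted
    surface-expression score estimation with wild-type/nonsense anchoring,
    LOWESS-residual outlier statistics for per-position rescue effects
    (Mann-Whitney U with Benjamini-Hochberg FDR), and annotation utilities
    (regions, clinical classes, predictor AUROC, hydrophobicity preference,
    ligand distances from a structure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
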