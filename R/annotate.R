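# Annotation of variant score tables: topology regions, clinical classes,
# variant-effect predictor scores and AUROC, per-position hydrophobicity
# preference, and minimum ligand distances from a structure.

#' Kyte-Doolittle hydropathy scale
#'
#' Published hydropathy values per residue (positive = hydrophobic).
#' @export
kyte_doolittle <- c(
  A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
  M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3
)

#' Validate a region table
#'
#' @param regions tibble with columns `region`, `start`, `end` (1-based
#'   inclusive residue intervals, e.g. the N-terminus, TM1..TM7, loops, H8
#'   and C-terminus of a GPCR).
#' @return the validated tibble (invisibly usable in pipes).
#' @export
region_table <- function(regions) {
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end)) stop("region start must be <= end")
  r <- dplyr::arrange(regions, .data$start)
  if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) {
    stop("region intervals must not overlap")
  }
  tibble::as_tibble(regions)
}

#' Assign residue positions to regions
#'
#' @param position integer residue positions.
#' @param regions a [region_table()].
#' @return character region labels; positions outside all intervals get
#'   `"unassigned"`.
#' @export
assign_region <- function(position, regions) {
  regions <- region_table(regions)
  vapply(position, function(p) {
    if (is.na(p)) return(NA_character_)
    hit <- which(regions$start <= p & p <= regions$end)
    if (length(hit) == 0) "unassigned" else regions$region[hit[1]]
  }, character(1))
}

#' Compare two score groups (Mann-Whitney U with summaries)
#'
#' @param scores_a,scores_b numeric score groups.
#' @return one-row tibble with `statistic`, `p.value`, group sizes, medians
#'   and quartiles.
#' @export
group_compare <- function(scores_a, scores_b) {
  tst <- mann_whitney_u(scores_a, scores_b)
  qa <- stats::quantile(scores_a, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  qb <- stats::quantile(scores_b, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  tibble::tibble(
    statistic = tst$statistic, p.value = tst$p.value,
    n_a = tst$n_a, n_b = tst$n_b,
    median_a = qa[2], median_b = qb[2],
    q1_a = qa[1], q3_a = qa[3], q1_b = qb[1], q3_b = qb[3]
  )
}

#' Per-position hydrophobicity preference
#'
#' Spearman rank correlation (midranks for ties) between the mutant
#' residue's hydrophobicity and the variant score, per position, over
#' missense variants. Invariant to affine rescaling of the scale.
#'
#' @param score_table tibble with `position`, `mut_aa`, `score` (missense
#'   rows are used).
#' @param scale named residue-to-hydrophobicity vector.
#' @param min_n minimum scored substitutions per position (default 5;
#'   positions below it get NA).
#' @return tibble with `position`, `n`, `rho`.
#' @export
hydrophobicity_preference <- function(score_table, scale = kyte_doolittle,
                                      min_n = 5) {
  if ("vclass" %in% names(score_table)) {
    score_table <- dplyr::filter(score_table, .data$vclass == "missense")
  }
  score_table %>%
    dplyr::filter(!is.na(.data$score), .data$mut_aa %in% names(scale)) %>%
    dplyr::summarise(
      n = dplyr::n(),
      rho = if (dplyr::n() >= min_n) {
        stats::cor(scale[.data$mut_aa], .data$score, method = "spearman")
      } else NA_real_,
      .by = "position"
    ) %>%
    dplyr::arrange(.data$position)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counting one half (the Mann-Whitney form). Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric predictor scores (higher = more positive).
#' @param labels logical (or 0/1) class labels.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)) # 0.75
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Minimum ligand distance per residue
#'
#' Minimum Euclidean distance over all heavy-atom pairs between each residue
#' and a ligand entity in a PDB coordinate file. The first model is used;
#' alternate locations other than `""`/`"A"` and hydrogens are discarded.
#'
#' @param pdb_file path to a PDB file.
#' @param positions residue numbers to annotate.
#' @param ligand ligand selector: residue name (`resid`, e.g. a peptide
#'   hormone's three-letter code) or chain ID when `ligand_is_chain`.
#' @param chain optional chain ID restricting the protein residues.
#' @param ligand_is_chain if `TRUE`, `ligand` names a chain rather than a
#'   residue name (for peptide ligands deposited as their own chain).
#' @return tibble with `position` and `min_dist` (Angstrom; NA for residues
#'   not resolved in the model).
#' @export
min_ligand_distance <- function(pdb_file, positions, ligand, chain = NULL,
                                ligand_is_chain = FALSE) {
  pdb <- bio3d::read.pdb(pdb_file)
  atoms <- pdb$atom
  atoms <- atoms[atoms$alt %in% c("", "A", NA), ]
  elesy <- if ("elesy" %in% names(atoms)) atoms$elesy else
    substring(trimws(atoms$elety), 1, 1)
  atoms <- atoms[is.na(elesy) | toupper(trimws(elesy)) != "H", ]

  lig <- if (ligand_is_chain) atoms[atoms$chain %in% ligand, ]
         else atoms[atoms$resid %in% ligand, ]
  if (nrow(lig) == 0) {
    stop("ligand '", ligand, "' not found in ", pdb_file)
  }
  prot <- atoms[atoms$type == "ATOM", ]
  if (!is.null(chain)) prot <- prot[prot$chain %in% chain, ]
  if (ligand_is_chain) prot <- prot[!(prot$chain %in% ligand), ]
  lm <- as.matrix(lig[, c("x", "y", "z")])
  tibble::tibble(
    position = as.integer(positions),
    min_dist = vapply(positions, function(p) {
      res <- prot[prot$resno == p, c("x", "y", "z")]
      if (nrow(res) == 0) return(NA_real_)
      d2 <- outer(rowSums(res^2), rowSums(lm^2), "+") -
        2 * as.matrix(res) %*% t(lm)
      sqrt(max(0, min(d2)))
    }, numeric(1))
  )
}

CLINICAL_PRECEDENCE <- c("pathogenic", "likely_pathogenic", "NDI", "NSIAD",
                         "VUS", "likely_benign", "benign", "gnomAD")

#' Annotate a variant score table
#'
#' Left-joins user-supplied annotations onto the score table: clinical
#' classes (named lists of variant keys, resolved by a fixed precedence when
#' a variant appears in several), predictor score tables (one column each),
#' region labels and a predicted-pathogenic flag at a predictor cut-off.
#' Unmatched variants retain NA.
#'
#' @param score_table per-variant score tibble (keyed by `variant`).
#' @param clinical named list of character vectors of variant keys; names
#'   are classes. Precedence (highest first): pathogenic, likely_pathogenic,
#'   NDI, NSIAD, VUS, likely_benign, benign, gnomAD.
#' @param predictors named list of tibbles with columns `variant`, `score`;
#'   each becomes a column named after the list element. Duplicate variant
#'   keys in a predictor table are an error.
#' @param regions optional [region_table()].
#' @param pathogenic_predictor name of the predictor column used for the
#'   `predicted_pathogenic` flag (scores >= `pathogenic_cutoff`).
#' @param pathogenic_cutoff flag threshold (default 0.564).
#' @return the annotated tibble.
#' @export
enrich_table <- function(score_table, clinical = list(), predictors = list(),
                         regions = NULL, pathogenic_predictor = NULL,
                         pathogenic_cutoff = 0.564) {
  out <- tibble::as_tibble(score_table)
  if (length(clinical) > 0) {
    unknown <- setdiff(names(clinical), CLINICAL_PRECEDENCE)
    if (length(unknown) > 0) {
      stop("unknown clinical class(es): ", paste(unknown, collapse = ", "))
    }
    cls <- rep(NA_character_, nrow(out))
    for (cl in rev(CLINICAL_PRECEDENCE)) { # highest precedence wins last
      if (!is.null(clinical[[cl]])) {
        cls[out$variant %in% clinical[[cl]]] <- cl
      }
    }
    out$clinical_class <- cls
  }
  for (nm in names(predictors)) {
    tbl <- predictors[[nm]]
    if (anyDuplicated(tbl$variant)) {
      stop("duplicate variant keys in predictor table '", nm, "'")
    }
    out <- dplyr::left_join(
      out, stats::setNames(tbl[, c("variant", "score")], c("variant", nm)),
      by = "variant")
  }
  if (!is.null(regions)) {
    out$region <- assign_region(out$position, regions)
  }
  if (!is.null(pathogenic_predictor)) {
    if (!pathogenic_predictor %in% names(out)) {
      stop("predictor column '", pathogenic_predictor, "' not found")
    }
    out$predicted_pathogenic <- out[[pathogenic_predictor]] >= pathogenic_cutoff
  }
  out
}
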