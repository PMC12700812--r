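# Surface-expression score estimation from binned barcode counts:
# read tallies -> per-bin cell estimates -> per-variant aggregation ->
# cell-weighted raw scores -> wild-type/nonsense anchored normalization ->
# replicate filtering and combination -> expression categories.

.group_cols <- function(x) intersect(c("replicate", "condition"), names(x))

#' Tally reads against a barcode whitelist
#'
#' Exact-match counting of barcode reads against the whitelist from the
#' barcode-variant association; non-matching sequences are tallied
#' separately and reported as the `unmatched` attribute.
#'
#' @param reads tibble with columns `read`, `bin` and optionally
#'   `replicate`/`condition`, or a character vector of reads (taken as one
#'   bin).
#' @param whitelist character vector of valid barcodes.
#' @return tibble of per-bin counts (`barcode`, `bin`, `reads`, ...), with
#'   attribute `unmatched` giving the number of non-matching reads.
#' @export
tally_barcodes <- function(reads, whitelist) {
  if (length(whitelist) == 0) stop("whitelist must be non-empty")
  if (is.character(reads)) reads <- tibble::tibble(read = reads, bin = 1L)
  ok <- !is.na(reads$read) & nzchar(reads$read)
  if (any(!ok)) {
    message(sum(!ok), " malformed read record(s) skipped")
    reads <- reads[ok, ]
  }
  matched <- reads$read %in% whitelist
  counts <- reads[matched, ] %>%
    dplyr::count(dplyr::across(dplyr::all_of(c("read", "bin", .group_cols(reads)))),
                 name = "reads") %>%
    dplyr::rename(barcode = "read")
  attr(counts, "unmatched") <- sum(!matched)
  counts
}

#' Estimate cells per barcode and bin
#'
#' Converts read counts to estimated cell counts: a barcode's share of a
#' bin's reads, multiplied by the number of cells sorted into that bin.
#' Conservation holds by construction: summing estimated cells over barcodes
#' recovers `cells_sorted` for every bin with reads.
#'
#' @param counts tibble (`barcode`, `bin`, `reads`, and optionally
#'   `replicate`, `condition`).
#' @param bins bin metadata tibble (`bin`, `cells_sorted`, `fluor`, matching
#'   grouping columns).
#' @return `counts` with a `cells` column appended.
#' @export
estimate_cells <- function(counts, bins) {
  gc <- .group_cols(counts)
  totals <- counts %>%
    dplyr::summarise(total_reads = sum(.data$reads), .by = dplyr::all_of(c("bin", gc)))
  check <- bins %>%
    dplyr::left_join(totals, by = c("bin", gc)) %>%
    dplyr::filter(.data$cells_sorted > 0,
                  is.na(.data$total_reads) | .data$total_reads == 0)
  if (nrow(check) > 0) {
    stop("inconsistent experiment: bin ", check$bin[1],
         " has cells_sorted > 0 but no reads")
  }
  counts %>%
    dplyr::left_join(totals, by = c("bin", gc)) %>%
    dplyr::left_join(dplyr::select(bins, dplyr::all_of(c("bin", gc, "cells_sorted"))),
                     by = c("bin", gc)) %>%
    dplyr::mutate(cells = .data$reads / .data$total_reads * .data$cells_sorted) %>%
    dplyr::select(-"total_reads", -"cells_sorted")
}

#' Aggregate barcode-level cell estimates to variants
#'
#' Sums estimated cells over all barcodes coding for the same amino-acid
#' variant. Barcodes missing from the map are excluded and tallied in the
#' `skipped_barcodes` attribute.
#'
#' @param cells output of [estimate_cells()].
#' @param map barcode-variant map (tibble with `barcode`, `variant` and
#'   variant identity columns).
#' @return per-variant, per-bin cell estimates with `n_barcodes`.
#' @export
aggregate_variants <- function(cells, map) {
  gc <- .group_cols(cells)
  known <- cells$barcode %in% map$barcode
  skipped <- sum(!known)
  out <- cells[known, ] %>%
    dplyr::inner_join(
      dplyr::select(map, dplyr::any_of(c("barcode", "variant", "position",
                                         "wt_aa", "mut_aa", "vclass"))),
      by = "barcode") %>%
    dplyr::summarise(
      cells = sum(.data$cells),
      n_barcodes = dplyr::n_distinct(.data$barcode),
      .by = dplyr::all_of(c("variant", "position", "wt_aa", "mut_aa",
                            "vclass", "bin", gc))
    ) %>%
    dplyr::mutate(n_barcodes = max(.data$n_barcodes),
                  .by = dplyr::all_of(c("variant", gc)))
  attr(out, "skipped_barcodes") <- skipped
  out
}

#' Cell-weighted raw surface-expression score
#'
#' The raw score of a variant is the cell-count-weighted mean of the per-bin
#' log10 geometric-mean fluorescence values:
#' `sum(cells_i * fluor_i) / sum(cells_i)` over the four bins.
#'
#' @param cells non-negative cell counts per bin.
#' @param fluor per-bin log10 fluorescence (NA allowed for empty bins with
#'   zero cells).
#' @return the raw score in log10 fluorescence units, or `NA` when no cells
#'   were observed.
#' @export
#' @examples
#' raw_score(c(10, 20, 30, 40), c(1, 2, 3, 4)) # 3
raw_score <- function(cells, fluor) {
  stopifnot(length(cells) == length(fluor))
  if (any(cells < 0, na.rm = TRUE)) stop("cells must be non-negative")
  w <- ifelse(is.na(cells), 0, cells)
  tot <- sum(w)
  if (tot == 0) return(NA_real_)
  sum(w * ifelse(w > 0, fluor, 0)) / tot
}

#' Per-variant raw scores from aggregated cells
#'
#' @param agg output of [aggregate_variants()].
#' @param bins bin metadata (for the per-bin `fluor` values).
#' @return one row per variant (per replicate/condition) with `raw` and
#'   `total_cells`.
#' @export
variant_raw_scores <- function(agg, bins) {
  gc <- .group_cols(agg)
  agg %>%
    dplyr::left_join(dplyr::select(bins, dplyr::all_of(c("bin", gc, "fluor"))),
                     by = c("bin", gc)) %>%
    dplyr::summarise(
      raw = raw_score(.data$cells, .data$fluor),
      total_cells = sum(.data$cells),
      n_barcodes = max(.data$n_barcodes),
      .by = dplyr::all_of(c("variant", "position", "wt_aa", "mut_aa",
                            "vclass", gc))
    )
}

#' Anchor-normalize raw scores
#'
#' Rescales raw scores so the wild-type genotype is 1 and the median of
#' early nonsense variants (premature stops at positions up to
#' `max_stop_pos`) is 0. Applied within each replicate and condition, since
#' fluorescence units differ across sorts. Affine-equivariant: any positive
#' affine transform of the bin fluorescence axis leaves normalized scores
#' unchanged.
#'
#' @param raw_tbl output of [variant_raw_scores()].
#' @param max_stop_pos latest stop position counted as an unambiguous
#'   loss-of-function anchor (default 299: stops before the 300th residue).
#' @return `raw_tbl` with a `norm_score` column.
#' @export
normalize_scores <- function(raw_tbl, max_stop_pos = 299) {
  gc <- .group_cols(raw_tbl)
  raw_tbl %>%
    dplyr::mutate(
      wt_raw = {
        w <- .data$raw[.data$vclass == "wildtype"]
        if (length(w) != 1 || is.na(w)) {
          stop("normalization requires exactly one scored wild-type genotype")
        }
        w
      },
      ns_raw = {
        v <- .data$raw[.data$vclass == "nonsense" &
                         .data$position <= max_stop_pos]
        v <- v[!is.na(v)]
        if (length(v) == 0) stop("no scored early-nonsense anchor variants")
        stats::median(v)
      },
      .by = dplyr::all_of(gc)
    ) %>%
    dplyr::mutate(norm_score = {
      if (any(abs(.data$wt_raw - .data$ns_raw) < 1e-12)) {
        stop("degenerate anchors: wild-type and nonsense medians coincide")
      }
      (.data$raw - .data$ns_raw) / (.data$wt_raw - .data$ns_raw)
    }) %>%
    dplyr::select(-"wt_raw", -"ns_raw")
}

#' Filter replicates and combine scores
#'
#' A replicate contributes to a variant's combined score only when that
#' variant's estimated cell total in the replicate reaches `min_cells`.
#' The combined score is the unweighted mean over contributing replicates;
#' `sem` is the sample s.d. over replicates divided by `sqrt(n)`. A variant
#' is high confidence when at least `min_replicates` replicates contribute.
#'
#' @param norm_tbl per-replicate normalized scores
#'   (from [normalize_scores()]).
#' @param min_cells minimum estimated cells per replicate (default 50).
#' @param min_replicates replicates required for `high_confidence`.
#' @return one row per variant (per condition) with `score`, `sem`,
#'   `n_replicates`, `n_barcodes`, `high_confidence`.
#' @export
filter_and_combine <- function(norm_tbl, min_cells = 50, min_replicates = 2) {
  gc <- setdiff(.group_cols(norm_tbl), "replicate")
  norm_tbl %>%
    dplyr::filter(!is.na(.data$norm_score), .data$total_cells >= min_cells) %>%
    dplyr::summarise(
      score = mean(.data$norm_score),
      sem = stats::sd(.data$norm_score) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      n_barcodes = max(.data$n_barcodes),
      total_cells = sum(.data$total_cells),
      .by = dplyr::all_of(c("variant", "position", "wt_aa", "mut_aa",
                            "vclass", gc))
    ) %>%
    dplyr::mutate(high_confidence = .data$n_replicates >= min_replicates)
}

#' Expression category thresholds from anchor distributions
#'
#' The poor/moderate boundary is the 95th percentile of truncation
#' (nonsense) scores; the moderate/well boundary is the 5th percentile of
#' synonymous wild-type scores (the bottom 95th percentile). Percentiles use
#' linear interpolation between order statistics (quantile type 7).
#'
#' @param truncation_scores,synonymous_scores numeric anchor score sets
#'   (at least 20 each).
#' @return list with `t_low` and `t_high`.
#' @export
expression_thresholds <- function(truncation_scores, synonymous_scores) {
  truncation_scores <- truncation_scores[!is.na(truncation_scores)]
  synonymous_scores <- synonymous_scores[!is.na(synonymous_scores)]
  if (length(truncation_scores) < 20 || length(synonymous_scores) < 20) {
    stop("need at least 20 scores in each anchor set")
  }
  t_low <- stats::quantile(truncation_scores, 0.95, names = FALSE, type = 7)
  t_high <- stats::quantile(synonymous_scores, 0.05, names = FALSE, type = 7)
  if (t_low >= t_high) {
    stop(sprintf(paste0("threshold inversion: 95th pct of truncations (%.3f) ",
                        ">= 5th pct of synonymous (%.3f); anchor sets do not ",
                        "separate"), t_low, t_high))
  }
  list(t_low = t_low, t_high = t_high)
}

#' Categorize scores as poorly/moderately/well expressed
#'
#' @param score numeric scores.
#' @param t_low,t_high category thresholds (see [expression_thresholds()]).
#' @return factor with levels `poor` (< t_low), `moderate`, `well`
#'   (>= t_high); `NA` scores stay `NA`.
#' @export
categorize <- function(score, t_low, t_high) {
  factor(dplyr::case_when(
    is.na(score) ~ NA_character_,
    score < t_low ~ "poor",
    score >= t_high ~ "well",
    TRUE ~ "moderate"
  ), levels = c("poor", "moderate", "well"))
}

#' Score a sort-seq experiment end to end
#'
#' Runs the full estimator for each replicate and condition present in the
#' inputs: cell estimation, aggregation to variants through the barcode map,
#' cell-weighted raw scores, per-replicate anchor normalization, replicate
#' filtering/combination, and expression categories (thresholds derived per
#' condition from the nonsense and synonymous anchor sets).
#'
#' @param counts per-bin barcode read counts (`barcode`, `bin`, `reads`,
#'   `replicate`, `condition`).
#' @param bins bin metadata (`bin`, `cells_sorted`, `fluor`, `replicate`,
#'   `condition`).
#' @param map barcode-variant map.
#' @param min_cells,min_replicates see [filter_and_combine()].
#' @param max_stop_pos see [normalize_scores()].
#' @return combined per-variant score table (one row per variant and
#'   condition) with a `category` column and attributes `replicates` (the
#'   per-replicate normalized table) and `thresholds` (per condition).
#' @export
score_experiment <- function(counts, bins, map, min_cells = 50,
                             min_replicates = 2, max_stop_pos = 299) {
  per_rep <- counts %>%
    estimate_cells(bins) %>%
    aggregate_variants(map) %>%
    variant_raw_scores(bins) %>%
    normalize_scores(max_stop_pos = max_stop_pos)
  combined <- filter_and_combine(per_rep, min_cells = min_cells,
                                 min_replicates = min_replicates)
  thresholds <- combined %>%
    dplyr::group_by(dplyr::across(dplyr::any_of("condition"))) %>%
    dplyr::group_modify(function(d, g) {
      th <- expression_thresholds(d$score[d$vclass == "nonsense"],
                                  d$score[d$vclass == "synonymous"])
      tibble::tibble(t_low = th$t_low, t_high = th$t_high)
    }) %>%
    dplyr::ungroup()
  combined <- if ("condition" %in% names(combined)) {
    dplyr::left_join(combined, thresholds, by = "condition")
  } else {
    dplyr::cross_join(combined, thresholds)
  }
  combined <- combined %>%
    dplyr::mutate(category = categorize(.data$score, .data$t_low, .data$t_high)) %>%
    dplyr::select(-"t_low", -"t_high")
  attr(combined, "replicates") <- per_rep
  attr(combined, "thresholds") <- thresholds
  combined
}
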