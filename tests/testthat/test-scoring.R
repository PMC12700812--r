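# The bin-weighted score estimator and its normalization/filtering contract.

make_bins <- function(fluor = c(1, 2, 3, 4), cells = c(1e5, 1e5, 1e5, 1e5)) {
  tibble::tibble(bin = 1:4, cells_sorted = cells, fluor = fluor)
}

test_that("read shares convert to cells and conserve the sorted totals", {
  counts <- tibble::tibble(
    barcode = c("a", "b", "a"),
    bin = c(1L, 1L, 3L),
    reads = c(100L, 900L, 50L)
  )
  bins <- make_bins(cells = c(1e6, 0, 2e4, 0))
  cells <- estimate_cells(counts, bins)
  expect_equal(cells$cells[cells$barcode == "a" & cells$bin == 1], 1e5)
  expect_equal(cells$cells[cells$barcode == "b" & cells$bin == 1], 9e5)
  # conservation per bin
  tot <- dplyr::summarise(cells, s = sum(cells), .by = bin)
  expect_equal(tot$s[tot$bin == 1], 1e6)
  expect_equal(tot$s[tot$bin == 3], 2e4)
  # cells sorted but no reads is an inconsistent experiment
  bad_bins <- make_bins(cells = c(1e6, 5e5, 2e4, 0))
  expect_error(estimate_cells(counts, bad_bins), "inconsistent")
})

test_that("cells aggregate over barcodes of the same variant", {
  cells <- tibble::tibble(
    barcode = c("a", "b", "c"),
    bin = 1L, reads = 1L,
    cells = c(10, 30, 5)
  )
  map <- tibble::tibble(barcode = c("a", "b"), variant = "A1V",
                        position = 1L, wt_aa = "A", mut_aa = "V",
                        vclass = "missense")
  agg <- aggregate_variants(cells, map)
  expect_equal(agg$cells, 40)
  expect_equal(agg$n_barcodes, 2)
  expect_equal(attr(agg, "skipped_barcodes"), 1)
})

test_that("raw scores equal brute-force weighted means to 1e-12", {
  expect_equal(raw_score(c(0, 0, 7, 0), c(1, 2, 3, 4)), 3)
  expect_equal(raw_score(c(10, 20, 30, 40), c(1, 2, 3, 4)), 3)
  expect_equal(raw_score(c(5, 5, 5, 5), c(1, 2, 3, 4)), 2.5)
  expect_true(is.na(raw_score(c(0, 0, 0, 0), c(1, 2, 3, 4))))
  set.seed(11)
  for (i in 1:250) {
    cells <- stats::runif(4, 0, 100) * stats::rbinom(4, 1, 0.8)
    fluor <- sort(stats::rnorm(4, 3, 1))
    expect_equal(raw_score(cells, fluor), oracle_raw_score(cells, fluor),
                 tolerance = 1e-12)
    if (sum(cells) > 0) {
      sc <- raw_score(cells, fluor)
      expect_gte(sc, min(fluor))
      expect_lte(sc, max(fluor))
    }
  }
})

test_that("normalization anchors wild type at 1 and early stops at 0", {
  raw_tbl <- tibble::tibble(
    variant = c("WT", "A1*", "C2*", "D3*", "A1V"),
    position = c(NA, 1L, 2L, 3L, 1L),
    wt_aa = c(NA, "A", "C", "D", "A"),
    mut_aa = c(NA, "*", "*", "*", "V"),
    vclass = c("wildtype", "nonsense", "nonsense", "nonsense", "missense"),
    raw = c(4, 2.1, 2.0, 1.9, 3),
    total_cells = 100, n_barcodes = 1L
  )
  out <- normalize_scores(raw_tbl)
  expect_equal(out$norm_score[out$variant == "WT"], 1)
  expect_equal(stats::median(out$norm_score[out$vclass == "nonsense"]), 0)
  expect_equal(out$norm_score[out$variant == "A1V"], 0.5)
  # stops past the early-stop cutoff are not anchors
  late <- dplyr::mutate(raw_tbl, position = c(NA, 320L, 330L, 340L, 1L))
  expect_error(normalize_scores(late), "anchor")
})

test_that("normalized scores are invariant to affine fluorescence transforms", {
  cfg <- small_config(seed = 12, n_cells = 2e4, read_depth = 1e5,
                      n_replicates = 1)
  lib <- simulate_library(cfg)
  s <- simulate_sort(lib, "control", 1)
  norm_of <- function(bins) {
    estimate_cells(s$counts, bins) %>%
      aggregate_variants(lib$barcode_map) %>%
      variant_raw_scores(bins) %>%
      normalize_scores()
  }
  base <- norm_of(s$bins)
  shifted <- norm_of(dplyr::mutate(s$bins, fluor = 2.5 * fluor + 7))
  expect_equal(base$norm_score, shifted$norm_score, tolerance = 1e-9)
})

test_that("the cell filter gates replicates and combining averages the rest", {
  norm_tbl <- tibble::tibble(
    variant = "A1V", position = 1L, wt_aa = "A", mut_aa = "V",
    vclass = "missense",
    replicate = 1:4,
    raw = 0, n_barcodes = 2L,
    total_cells = c(200, 49, 120, 80),
    norm_score = c(0.2, 0.9, 0.4, 0.3)
  )
  out <- filter_and_combine(norm_tbl, min_cells = 50, min_replicates = 2)
  expect_equal(out$n_replicates, 3) # the 49-cell replicate is excluded
  expect_equal(out$score, mean(c(0.2, 0.4, 0.3)))
  expect_equal(out$sem, stats::sd(c(0.2, 0.4, 0.3)) / sqrt(3))
  expect_true(out$high_confidence)
  # boundary: exactly 50 cells contributes
  fifty <- dplyr::mutate(norm_tbl, total_cells = c(50, 49, 49, 49))
  expect_equal(filter_and_combine(fifty)$n_replicates, 1)
  expect_false(filter_and_combine(fifty)$high_confidence)
  # two passing replicates: plain mean
  two <- dplyr::mutate(norm_tbl, total_cells = c(100, 100, 0, 0),
                       norm_score = c(0.2, 0.4, 9, 9))
  expect_equal(filter_and_combine(two)$score, 0.3)
})

test_that("category thresholds recover the anchor-distribution percentiles", {
  set.seed(21)
  trunc_scores <- stats::rnorm(4000, 0, 0.1)
  syn_scores <- stats::rnorm(4000, 1, 0.05)
  th <- expression_thresholds(trunc_scores, syn_scores)
  # generating-distribution quantiles, frozen: qnorm(.95)*0.1, 1-qnorm(.95)*0.05
  expect_equal(th$t_low, 0.1644854, tolerance = 0.05)
  expect_equal(th$t_high, 0.9177573, tolerance = 0.02)
  cats <- categorize(c(th$t_low - 0.01, th$t_low, th$t_high, NA),
                     th$t_low, th$t_high)
  expect_equal(as.character(cats), c("poor", "moderate", "well", NA))
  expect_error(expression_thresholds(syn_scores, trunc_scores), "inversion")
  expect_error(expression_thresholds(trunc_scores[1:10], syn_scores), "20")
})

test_that("barcode tallying is exact-match against the whitelist", {
  wl <- c("AAAA", "CCCC", "GGGG")
  reads <- tibble::tibble(
    read = c("AAAA", "AAAA", "CCCC", "AAAT", "TTTT"),
    bin = c(1L, 1L, 2L, 1L, 1L)
  )
  counts <- tally_barcodes(reads, wl)
  expect_equal(counts$reads[counts$barcode == "AAAA" & counts$bin == 1], 2)
  expect_equal(attr(counts, "unmatched"), 2) # one-substitution reads do not match
  set.seed(5)
  big <- tibble::tibble(
    read = c(sample(wl, 900, replace = TRUE), rep("NNNN", 100)),
    bin = 1L
  )
  out <- tally_barcodes(big, wl)
  expect_equal(sum(out$reads), 900)
  expect_equal(attr(out, "unmatched"), 100)
  expect_error(tally_barcodes(reads, character()), "whitelist")
})

test_that("scored experiments carry per-replicate and threshold attributes", {
  cfg <- small_config(seed = 13)
  ex <- simulate_experiment(cfg, conditions = "control")
  s <- score_experiment(ex$counts, ex$bins, ex$library$barcode_map,
                        min_cells = 20)
  expect_true(all(c("score", "sem", "n_replicates", "category") %in% names(s)))
  expect_equal(s$score[s$vclass == "wildtype"], 1)
  reps <- attr(s, "replicates")
  expect_equal(sort(unique(reps$replicate)), 1:2)
  th <- attr(s, "thresholds")
  expect_true(th$t_low < th$t_high)
  # anchors: combined nonsense median at 0 within estimation noise
  expect_lt(abs(stats::median(s$score[s$vclass == "nonsense"])), 0.02)
})
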