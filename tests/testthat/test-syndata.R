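# The generator's physical model and its sampling contracts.

test_that("folded fraction follows the two-state Boltzmann form", {
  expect_equal(folded_fraction(0, RT = 0.616), 0.5)
  expect_equal(folded_fraction(-50, RT = 0.616), 1, tolerance = 1e-12)
  # closed form evaluated independently and frozen
  expect_equal(folded_fraction(1, RT = 0.616), 0.1647397188459557,
               tolerance = 1e-12)
  dg <- seq(-6, 6, by = 0.25)
  expect_true(all(diff(folded_fraction(dg, RT = 0.616)) < 0))
  expect_error(folded_fraction(NA_real_), "finite")
  expect_error(folded_fraction(0, RT = 0), "RT")
})

test_that("expected fluorescence anchors and monotonicity hold", {
  expect_equal(expected_fluor(1, 4, 2), 4)
  expect_equal(expected_fluor(0, 4, 2), 2)
  expect_equal(expected_fluor(0.5, 4, 2), 3.703291378118661, tolerance = 1e-12)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(expected_fluor(p, 4, 2)) > 0))
  expect_error(expected_fluor(0.5, 2, 4), "fluor_max")
})

test_that("conditions shift free energies additively, sparing non-rescuable positions", {
  truth <- tibble::tibble(
    variant = c("A1V", "A2V", "A3*"), position = 1:3,
    vclass = c("missense", "missense", "nonsense"),
    ddg_var = c(2, 2, NA), rescuable = c(TRUE, FALSE, FALSE)
  )
  ctrl <- apply_condition(truth, "control", ddg_rescue = -3, dg_wt = -2)
  resc <- apply_condition(truth, "rescue", ddg_rescue = -3, dg_wt = -2)
  expect_equal(ctrl[1], 0)        # dg_wt + ddg_var
  expect_equal(resc[1], -3)       # rescued
  expect_equal(resc[2], ctrl[2])  # rescuable = FALSE: untouched
  expect_true(is.na(resc[3]))     # nonsense bypasses folding

  # zero perturbation: rescue equals control everywhere
  expect_equal(apply_condition(truth, "rescue", ddg_rescue = 0, dg_wt = -2),
               ctrl)
  # position-level exception rule
  truth2 <- dplyr::mutate(truth, rescuable = TRUE)
  r2 <- apply_condition(truth2, "rescue", ddg_rescue = -3,
                        nonrescuable_positions = 1L, dg_wt = -2)
  expect_equal(r2[1], ctrl[1])
  expect_equal(r2[2], -3)
  expect_error(apply_condition(truth, "warmer", ddg_rescue = -3),
               "unknown condition")
})

test_that("library generation is deterministic and respects variant invariants", {
  cfg <- small_config(seed = 3)
  lib1 <- simulate_library(cfg)
  lib2 <- simulate_library(cfg)
  expect_identical(lib1$truth, lib2$truth)
  expect_identical(lib1$barcode_map, lib2$barcode_map)

  tr <- lib1$truth
  expect_true(all(tr$position >= 1 & tr$position <= cfg$L, na.rm = TRUE))
  expect_true(all(tr$mut_aa[tr$vclass == "nonsense"] == "*"))
  expect_true(all(tr$ddg_var[tr$vclass %in% c("synonymous", "wildtype")] == 0))
  expect_false(any(duplicated(tr$variant)))
  expect_false(any(duplicated(lib1$barcode_map$barcode)))
  # every missense position carries all 19 substitutions
  mis <- dplyr::count(dplyr::filter(tr, vclass == "missense"), position)
  expect_true(all(mis$n == 19))
})

test_that("sorting conserves cells and reads and is seed-deterministic", {
  cfg <- small_config(seed = 5, n_cells = 2e4, read_depth = 1e5)
  lib <- simulate_library(cfg)
  s1 <- simulate_sort(lib, "control", 1)
  s2 <- simulate_sort(lib, "control", 1)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$bins, s2$bins)
  expect_equal(sum(s1$bins$cells_sorted), cfg$n_cells)
  expect_equal(sum(s1$counts$reads), cfg$read_depth)
  # distinct replicate and condition sub-streams
  s3 <- simulate_sort(lib, "control", 2)
  expect_false(identical(s1$counts, s3$counts))
  # realized bin fluor lies within its gate
  ok <- with(s1$bins, fluor >= gate_low & fluor < gate_high)
  expect_true(all(ok[s1$bins$cells_sorted > 0]))
})

test_that("a degenerate noiseless library sorts into a single bin", {
  cfg <- small_config(seed = 2, sigma_cell = 0, n_cells = 1e3,
                      read_depth = 1e4)
  lib <- single_barcode_library(config = cfg)
  s <- simulate_sort(lib, "control", 1)
  expect_equal(sum(s$bins$cells_sorted > 0), 1)
  expect_equal(sum(s$counts$reads), cfg$read_depth)
  expect_equal(length(unique(s$counts$bin)), 1)
})

test_that("bin occupancies of one genotype match Gaussian gate probabilities", {
  cfg <- small_config(seed = 9, n_cells = 2e5, read_depth = 1e5)
  lib <- single_barcode_library(ddg_var = 2, config = cfg)
  s <- simulate_sort(lib, "control", 1)
  mu <- ground_truth_expectations(lib, "control")$mu_fluor
  probs <- diff(stats::pnorm(c(-Inf, s$bins$gate_low[-1], Inf), mu,
                             cfg$sigma_cell))
  for (b in 1:4) {
    se <- sqrt(cfg$n_cells * probs[b] * (1 - probs[b]))
    expect_lt(abs(s$bins$cells_sorted[b] - cfg$n_cells * probs[b]), 3 * se + 1)
  }
})

test_that("long reads reproduce the map exactly at zero miscall rate", {
  lib <- simulate_library(small_config(seed = 4, L = 20))
  lr <- simulate_longreads(lib, miscall_rate = 0, frac_high_err = 0)
  expect_identical(simulate_longreads(lib, miscall_rate = 0, frac_high_err = 0),
                   lr)
  truth_call <- lib$barcode_map$codon_subs[match(lr$barcode,
                                                 lib$barcode_map$barcode)]
  expect_identical(lr$variant_call, truth_call)
  expect_true(all(table(lr$barcode) >= 1))
})

test_that("the miscall fraction matches its binomial expectation", {
  lib <- simulate_library(small_config(seed = 6, L = 40,
                                       barcodes_per_variant = 3,
                                       reads_per_barcode = 3))
  lr <- simulate_longreads(lib, miscall_rate = 0.2, frac_high_err = 0)
  truth_call <- lib$barcode_map$codon_subs[match(lr$barcode,
                                                 lib$barcode_map$barcode)]
  frac <- mean(lr$variant_call != truth_call)
  se <- sqrt(0.2 * 0.8 / nrow(lr))
  expect_gt(nrow(lr), 5e3)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("expected expression is monotone in ddG and rescue only helps", {
  cfg <- small_config(seed = 2, nonrescuable_positions = c(3, 7))
  lib <- simulate_library(cfg)
  ctrl <- ground_truth_expectations(lib, "control")
  resc <- ground_truth_expectations(lib, "rescue")
  mis <- dplyr::arrange(dplyr::filter(ctrl, vclass == "missense"), ddg_var)
  expect_true(all(diff(mis$mu_fluor) <= 0))
  # rescuable variants never lose folded fraction under the stabilizer
  r <- ctrl$rescuable & ctrl$vclass != "nonsense"
  expect_true(all(resc$p_fold[r] >= ctrl$p_fold[r]))
  expect_true(all(resc$p_fold[ctrl$position %in% c(3, 7) &
                                ctrl$vclass == "missense"] ==
                    ctrl$p_fold[ctrl$position %in% c(3, 7) &
                                  ctrl$vclass == "missense"]))
})

test_that("stronger stabilization widens the rescue gap mid-curve only", {
  # noise-free dose response: moderately expressed variants gain the most,
  # well-expressed variants barely move (sigmoid compression)
  cfg3 <- small_config(seed = 2, ddg_rescue = -3)
  cfg5 <- small_config(seed = 2, ddg_rescue = -5)
  lib3 <- simulate_library(cfg3)
  lib5 <- simulate_library(cfg5)
  expect_identical(lib3$truth$ddg_var, lib5$truth$ddg_var)
  gap <- function(lib) {
    c <- ground_truth_expectations(lib, "control")
    r <- ground_truth_expectations(lib, "rescue")
    tibble::tibble(p_ctrl = c$p_fold, gain = r$p_fold - c$p_fold,
                   vclass = c$vclass)
  }
  g3 <- gap(lib3)
  g5 <- gap(lib5)
  mid <- g3$vclass == "missense" & g3$p_ctrl > 0.05 & g3$p_ctrl < 0.6
  high <- g3$vclass == "missense" & g3$p_ctrl > 0.95
  expect_gt(mean(g5$gain[mid]), mean(g3$gain[mid]))
  expect_lt(mean(g5$gain[high]), 0.05)
})
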