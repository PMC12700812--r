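# Synthetic sort-seq generator under a two-state folding model with additive
# free-energy rescue. Every stochastic output is a pure function of
# (config, seed): sub-streams are derived from the config seed by fixed
# offsets per stage/replicate/condition.

CONDITIONS <- c("control", "rescue")

# deterministic sub-stream seed; kept below 2^31
.substream <- function(seed, stage, replicate = 0L, condition = 0L) {
  as.integer((as.numeric(seed) * 1009 + stage * 101159 +
                replicate * 1013 + condition * 523) %% 2147483587)
}

.condition_index <- function(condition) {
  i <- match(condition, CONDITIONS)
  if (is.na(i)) {
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(CONDITIONS, collapse = ", "))
  }
  i
}

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic sort-seq experiment: a
#' saturation library over an `L`-residue protein, a two-state folding model
#' mapping total folding free energy to folded fraction, a sigmoidal map from
#' folded fraction to log10 surface fluorescence, additive condition-level
#' stabilization (the pharmacological-chaperone / temperature rescue term)
#' with optional planted non-rescuable and extra-rescue positions, and a
#' four-bin sort with multinomial read sampling.
#'
#' @param L protein length in residues.
#' @param dg_wt baseline folding free energy of the wild type, kcal/mol
#'   (negative = stable; the default -2 is marginal stability).
#' @param RT thermal energy, kcal/mol (0.616 at 37 C).
#' @param ddg_mix_w weight of the near-neutral component of the missense
#'   ddG mixture.
#' @param ddg_mix_sd s.d. (kcal/mol) of the near-neutral Normal component.
#' @param ddg_mix_shape,ddg_mix_scale shape/scale of the destabilizing Gamma
#'   component. The default (mean 5, s.d. 1 kcal/mol) concentrates
#'   destabilized variants in the assay's informative window: control
#'   expression collapses to the poor peak of the bimodal score histogram
#'   while a few kcal/mol of rescue moves them onto the steep part of the
#'   sigmoid, keeping rescue effects in both directions within the dynamic
#'   range.
#' @param ddg_rescue condition-level stabilization in the rescue condition,
#'   kcal/mol (<= 0 for a stabilizer).
#' @param nonrescuable_positions residue indices at which the rescue term is
#'   withheld (binding-site / PTM-like positions).
#' @param extrarescue_positions residue indices receiving `ddg_extra` of
#'   additional stabilization in the rescue condition.
#' @param ddg_extra additional stabilization (kcal/mol, <= 0) at
#'   `extrarescue_positions`.
#' @param fluor_max,fluor_bg log10 fluorescence of a fully expressed and a
#'   null genotype.
#' @param sigma_cell per-cell log10 fluorescence s.d.
#' @param barcodes_per_variant mean of the Poisson in `1 + Pois(mean)`
#'   barcodes per variant (default gives a median of 5).
#' @param n_cells cells sorted per replicate and condition.
#' @param read_depth total short reads per replicate and condition.
#' @param n_bins number of sort bins; must be 4.
#' @param n_replicates replicates per condition.
#' @param miscall_rate fraction of long reads carrying a spurious extra
#'   nucleotide substitution.
#' @param frac_high_err fraction of long reads with an inflated estimated
#'   error rate (above the quality filters).
#' @param reads_per_barcode mean of the Poisson in `1 + Pois(mean)` long
#'   reads per barcode. In [simulate_longreads()] a function of the barcode
#'   count returning per-barcode read numbers may be supplied instead (for
#'   example a constant 2 reads everywhere).
#' @param seed integer seed; all stochastic outputs are pure functions of
#'   (config, seed).
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(L = 371,
                       dg_wt = -2,
                       RT = 0.616,
                       ddg_mix_w = 0.5,
                       ddg_mix_sd = 0.3,
                       ddg_mix_shape = 25,
                       ddg_mix_scale = 0.2,
                       ddg_rescue = -3,
                       nonrescuable_positions = integer(),
                       extrarescue_positions = integer(),
                       ddg_extra = 0,
                       fluor_max = 4,
                       fluor_bg = 2,
                       sigma_cell = 0.3,
                       barcodes_per_variant = 4,
                       n_cells = 5e5,
                       read_depth = 2e6,
                       n_bins = 4,
                       n_replicates = 4,
                       miscall_rate = 0.02,
                       frac_high_err = 0.05,
                       reads_per_barcode = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    "L must be a positive integer" = L >= 1,
    "RT must be > 0" = RT > 0,
    "n_bins must be 4" = n_bins == 4,
    "fluor_max must exceed fluor_bg" = fluor_max > fluor_bg,
    "ddg_rescue must be <= 0 for a stabilizer" = ddg_rescue <= 0,
    "ddg_extra must be <= 0" = ddg_extra <= 0,
    "ddg_mix_w must be in [0, 1]" = ddg_mix_w >= 0 && ddg_mix_w <= 1,
    "sigma_cell must be >= 0" = sigma_cell >= 0,
    "miscall_rate must be in [0, 1)" = miscall_rate >= 0 && miscall_rate < 1,
    "frac_high_err must be in [0, 1)" = frac_high_err >= 0 && frac_high_err < 1,
    "n_cells must be positive" = n_cells >= 1,
    "read_depth must be positive" = read_depth >= 1,
    "n_replicates must be positive" = n_replicates >= 1
  )
  if (any(nonrescuable_positions < 1 | nonrescuable_positions > L)) {
    stop("nonrescuable_positions must lie in [1, L]")
  }
  if (any(extrarescue_positions < 1 | extrarescue_positions > L)) {
    stop("extrarescue_positions must lie in [1, L]")
  }
  cfg$L <- as.integer(L)
  cfg$seed <- as.integer(seed)
  cfg$nonrescuable_positions <- as.integer(nonrescuable_positions)
  cfg$extrarescue_positions <- as.integer(extrarescue_positions)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  protein length L = %d, dG_wt = %.2f kcal/mol, RT = %.3f\n",
              x$L, x$dg_wt, x$RT))
  cat(sprintf("  rescue ddG = %.2f kcal/mol; %d non-rescuable, %d extra-rescue positions\n",
              x$ddg_rescue, length(x$nonrescuable_positions),
              length(x$extrarescue_positions)))
  cat(sprintf("  %g cells, %g reads, %d bins, %d replicates, seed %d\n",
              x$n_cells, x$read_depth, x$n_bins, x$n_replicates, x$seed))
  invisible(x)
}

#' Two-state folded fraction
#'
#' Boltzmann folded fraction of a two-state folder:
#' `1 / (1 + exp(dg_total / RT))`. Strictly decreasing in `dg_total`.
#'
#' @param dg_total total folding free energy, kcal/mol.
#' @param RT thermal energy, kcal/mol.
#' @return folded fraction in \[0, 1\].
#' @export
#' @examples
#' folded_fraction(0, RT = 0.616) # 0.5
folded_fraction <- function(dg_total, RT = 0.616) {
  if (RT <= 0) stop("RT must be > 0")
  if (any(!is.finite(dg_total))) stop("dg_total must be finite")
  1 / (1 + exp(dg_total / RT))
}

#' Expected log10 fluorescence of a genotype
#'
#' Linear mixing of fully-expressed and null fluorescence on the linear
#' scale, reported on the log10 axis:
#' `log10(p_fold * 10^fluor_max + (1 - p_fold) * 10^fluor_bg)`.
#'
#' @param p_fold folded fraction in \[0, 1\].
#' @param fluor_max,fluor_bg log10 fluorescence anchors.
#' @return expected log10 fluorescence; monotone increasing in `p_fold`.
#' @export
expected_fluor <- function(p_fold, fluor_max, fluor_bg) {
  if (fluor_max <= fluor_bg) stop("fluor_max must exceed fluor_bg")
  if (any(p_fold < 0 | p_fold > 1, na.rm = TRUE)) {
    stop("p_fold must lie in [0, 1]")
  }
  log10(p_fold * 10^fluor_max + (1 - p_fold) * 10^fluor_bg)
}

#' Apply a condition to ground-truth free energies
#'
#' Total folding free energy per variant under a condition. The rescue
#' condition adds a constant stabilization `ddg_rescue` (plus `ddg_extra` at
#' extra-rescue positions) for rescuable variants only; the control condition
#' never alters the free energy.
#'
#' @param truth tibble with columns `position`, `ddg_var`, `rescuable`.
#' @param condition `"control"` or `"rescue"`.
#' @param ddg_rescue condition-level stabilization, kcal/mol (<= 0).
#' @param nonrescuable_positions positions at which rescue is withheld.
#' @param dg_wt baseline wild-type folding free energy.
#' @param extrarescue_positions,ddg_extra positions receiving additional
#'   stabilization, and its magnitude (<= 0).
#' @return numeric vector of `dg_total`, kcal/mol (NA for nonsense variants,
#'   which are assigned zero folded fraction directly).
#' @export
apply_condition <- function(truth, condition, ddg_rescue,
                            nonrescuable_positions = integer(),
                            dg_wt = -2,
                            extrarescue_positions = integer(),
                            ddg_extra = 0) {
  i <- .condition_index(condition)
  if (ddg_rescue > 0) stop("ddg_rescue must be <= 0 for a stabilizer")
  shift <- rep(0, nrow(truth))
  if (i == 2L) {
    eligible <- truth$rescuable & !(truth$position %in% nonrescuable_positions)
    eligible[is.na(eligible)] <- TRUE # the WT genotype (position NA) folds
    shift[eligible] <- ddg_rescue +
      ddg_extra * (truth$position[eligible] %in% extrarescue_positions)
  }
  dg <- dg_wt + truth$ddg_var + shift
  dg[truth$vclass == "nonsense"] <- NA_real_
  dg
}

#' Expected folded fraction and fluorescence under a condition
#'
#' @param lib a `sim_library` from [simulate_library()].
#' @param condition `"control"` or `"rescue"`.
#' @return the ground-truth tibble with `dg_total`, `p_fold` and `mu_fluor`
#'   columns for the requested condition appended.
#' @export
ground_truth_expectations <- function(lib, condition) {
  cfg <- lib$config
  truth <- lib$truth
  dg <- apply_condition(truth, condition,
                        ddg_rescue = cfg$ddg_rescue,
                        nonrescuable_positions = cfg$nonrescuable_positions,
                        dg_wt = cfg$dg_wt,
                        extrarescue_positions = cfg$extrarescue_positions,
                        ddg_extra = cfg$ddg_extra)
  p_fold <- ifelse(is.na(dg), 0, folded_fraction(ifelse(is.na(dg), 0, dg), cfg$RT))
  truth %>%
    dplyr::mutate(
      condition = condition,
      dg_total = dg,
      p_fold = p_fold,
      mu_fluor = expected_fluor(p_fold, cfg$fluor_max, cfg$fluor_bg)
    )
}

# ---- library generation -----------------------------------------------------

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

.codons_for <- function(aa) {
  names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == aa]
}

.random_barcodes <- function(n, width = 16) {
  draw <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, character(1))
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

# codon-level substitutions for one variant on the wild-type CDS
.codon_substitutions <- function(wt_codon, mut_codon, position) {
  diffs <- which(strsplit(wt_codon, "")[[1]] != strsplit(mut_codon, "")[[1]])
  if (length(diffs) == 0) return("")
  nt_pos <- (position - 1L) * 3L + diffs
  ref <- substring(wt_codon, diffs, diffs)
  alt <- substring(mut_codon, diffs, diffs)
  paste(paste0(nt_pos, ref, ">", alt), collapse = ";")
}

#' Simulate a saturation variant library with ground truth
#'
#' Generates a random coding sequence of length `L` codons, the full set of
#' single amino-acid variants (all missense, one nonsense and, where the
#' wild-type codon has a synonym, one synonymous variant per position, plus
#' the wild-type genotype), per-variant fold-stability ddG values drawn from
#' the configured mixture, and a barcode-variant map with a median of
#' `1 + Pois(barcodes_per_variant)` barcodes per variant. Each barcode
#' carries its own codon-level substitution set, so long-read consensus and
#' support rules can be exercised downstream.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_library`: a list with elements `truth`
#'   (tibble of variants with `ddg_var` and `rescuable`), `barcode_map`
#'   (tibble keyed by barcode), `cds` (wild-type coding sequence) and
#'   `config`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, 1L))
  L <- config$L

  wt_aa <- sample(AMINO_ACIDS, L, replace = TRUE)
  wt_codon <- vapply(wt_aa, function(a) sample(.codons_for(a), 1), character(1))
  cds <- paste(wt_codon, collapse = "")

  per_pos <- purrr::map(seq_len(L), function(p) {
    mis <- setdiff(AMINO_ACIDS, wt_aa[p])
    mut <- c(mis, "*", if (length(.codons_for(wt_aa[p])) > 1) "=")
    tibble::tibble(position = p, wt_aa = wt_aa[p], mut_aa = mut)
  })
  truth <- dplyr::bind_rows(per_pos) %>%
    dplyr::mutate(vclass = variant_class(.data$wt_aa, .data$mut_aa)) %>%
    dplyr::bind_rows(tibble::tibble(
      position = NA_integer_, wt_aa = NA_character_,
      mut_aa = NA_character_, vclass = "wildtype"
    )) %>%
    dplyr::mutate(variant = format_variant_key(.data$wt_aa, .data$position,
                                               .data$mut_aa)) %>%
    dplyr::relocate("variant")

  n <- nrow(truth)
  neutral <- stats::runif(n) < config$ddg_mix_w
  ddg <- ifelse(neutral,
                stats::rnorm(n, 0, config$ddg_mix_sd),
                stats::rgamma(n, shape = config$ddg_mix_shape,
                              scale = config$ddg_mix_scale))
  ddg[truth$vclass %in% c("synonymous", "wildtype")] <- 0
  ddg[truth$vclass == "nonsense"] <- NA_real_
  truth$ddg_var <- ddg
  truth$rescuable <- truth$vclass != "nonsense" &
    !(truth$position %in% config$nonrescuable_positions)
  truth$rescuable[truth$vclass == "wildtype"] <- TRUE

  # barcode map: each barcode draws its own codon for the target residue
  n_bc_per_var <- 1L + stats::rpois(n, config$barcodes_per_variant)
  map <- truth[rep(seq_len(n), n_bc_per_var),
               c("variant", "position", "wt_aa", "mut_aa", "vclass")]
  map$barcode <- .random_barcodes(nrow(map))

  pick_codon <- function(position, mut_aa, vclass) {
    if (vclass == "wildtype") return(NA_character_)
    wt <- wt_codon[position]
    pool <- switch(vclass,
      nonsense = .codons_for("*"),
      synonymous = setdiff(.codons_for(wt_aa[position]), wt),
      missense = .codons_for(mut_aa)
    )
    pool[sample.int(length(pool), 1)]
  }
  map$codon_subs <- purrr::pmap_chr(
    list(map$position, map$mut_aa, map$vclass),
    function(p, m, v) {
      if (v == "wildtype") return("")
      .codon_substitutions(wt_codon[p], pick_codon(p, m, v), p)
    }
  )
  map$n_nt_changes <- ifelse(map$codon_subs == "", 0L,
                             stringr::str_count(map$codon_subs, ";") + 1L)
  map <- tibble::as_tibble(map) %>% dplyr::relocate("barcode")

  structure(list(truth = truth, barcode_map = map, cds = cds, config = config),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library>\n")
  cat(sprintf("  %d variants over %d residues; %d barcodes (median %d per variant)\n",
              nrow(x$truth), x$config$L, nrow(x$barcode_map),
              stats::median(table(x$barcode_map$variant))))
  invisible(x)
}

# ---- sorting ----------------------------------------------------------------

#' Simulate a four-bin sort with read sampling
#'
#' Draws `n_cells` cells multinomially across the barcode library, gives each
#' cell a Normal log10 fluorescence around its genotype mean, gates cells
#' into four contiguous bins placed at the quartiles of the realized
#' fluorescence distribution (so bins are similarly populated), and samples
#' `read_depth` sequencing reads multinomially over each bin's cell
#' composition. The realized per-bin `fluor` is the mean log10 fluorescence
#' of that bin's cells. Deterministic given (config, condition, replicate).
#'
#' @param lib a `sim_library`.
#' @param condition `"control"` or `"rescue"`.
#' @param replicate replicate index (1-based).
#' @return a list with `bins` (tibble: `bin`, `gate_low`, `gate_high`,
#'   `cells_sorted`, `fluor`, `replicate`, `condition`) and `counts`
#'   (tibble: `barcode`, `bin`, `reads`, `replicate`, `condition`; zero rows
#'   omitted).
#' @export
simulate_sort <- function(lib, condition = "control", replicate = 1L) {
  stopifnot(inherits(lib, "sim_library"))
  cfg <- lib$config
  ci <- .condition_index(condition)
  set.seed(.substream(cfg$seed, 2L, replicate, ci))

  exp_tbl <- ground_truth_expectations(lib, condition)
  mu <- exp_tbl$mu_fluor[match(lib$barcode_map$variant, exp_tbl$variant)]
  n_bc <- nrow(lib$barcode_map)
  if (n_bc == 0) stop("barcode map is empty")

  idx <- sample.int(n_bc, cfg$n_cells, replace = TRUE)
  fl <- stats::rnorm(cfg$n_cells, mu[idx], cfg$sigma_cell)

  gates <- stats::quantile(fl, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  bin <- findInterval(fl, gates) + 1L # [low, high) gates
  cells_sorted <- tabulate(bin, nbins = 4L)
  bin_fluor <- vapply(1:4, function(b) {
    if (cells_sorted[b] == 0) NA_real_ else mean(fl[bin == b])
  }, numeric(1))

  cell_counts <- matrix(tabulate((idx - 1L) * 4L + bin, nbins = n_bc * 4L),
                        nrow = 4L)
  reads_per_bin <- as.vector(stats::rmultinom(1, cfg$read_depth, cells_sorted))
  reads <- matrix(0L, nrow = 4L, ncol = n_bc)
  for (b in 1:4) {
    if (reads_per_bin[b] > 0 && cells_sorted[b] > 0) {
      reads[b, ] <- stats::rmultinom(1, reads_per_bin[b], cell_counts[b, ])
    }
  }

  gl <- c(-Inf, gates)
  gh <- c(gates, Inf)
  bins <- tibble::tibble(
    bin = 1:4, gate_low = gl, gate_high = gh,
    cells_sorted = cells_sorted, fluor = bin_fluor,
    replicate = as.integer(replicate), condition = condition
  )
  keep <- which(reads > 0)
  counts <- tibble::tibble(
    barcode = lib$barcode_map$barcode[(keep - 1L) %/% 4L + 1L],
    bin = as.integer((keep - 1L) %% 4L + 1L),
    reads = as.integer(reads[keep]),
    replicate = as.integer(replicate), condition = condition
  ) %>% dplyr::arrange(.data$barcode, .data$bin)
  list(bins = bins, counts = counts)
}

#' Simulate a full sort-seq experiment
#'
#' Runs [simulate_sort()] for every replicate and condition.
#'
#' @param config a [sim_config()].
#' @param conditions conditions to simulate.
#' @return an object of class `sort_experiment`: list with `library`, `bins`
#'   and `counts` (rows for all replicates and conditions).
#' @export
simulate_experiment <- function(config, conditions = CONDITIONS) {
  lib <- simulate_library(config)
  grid <- tidyr::expand_grid(condition = conditions,
                             replicate = seq_len(config$n_replicates))
  sorts <- purrr::pmap(grid, function(condition, replicate) {
    simulate_sort(lib, condition, replicate)
  })
  structure(list(
    library = lib,
    bins = dplyr::bind_rows(purrr::map(sorts, "bins")),
    counts = dplyr::bind_rows(purrr::map(sorts, "counts"))
  ), class = "sort_experiment")
}

# ---- long reads -------------------------------------------------------------

#' Simulate long-read records for barcode-variant association
#'
#' Emits at least one record per barcode (`1 + Pois(reads_per_barcode)`).
#' A fraction `miscall_rate` of records carries a spurious extra nucleotide
#' substitution, and a fraction `frac_high_err` carries an inflated estimated
#' error rate, so the downstream quality and consensus filters can be
#' exercised. Deterministic given (config, seed).
#'
#' @param lib a `sim_library`.
#' @param miscall_rate,frac_high_err,reads_per_barcode override the
#'   corresponding `sim_config` fields.
#' @return tibble with columns `barcode`, `variant_call` (semicolon-joined
#'   nucleotide substitutions, `""` for a wild-type read), `err_cds`,
#'   `err_bc`.
#' @export
simulate_longreads <- function(lib,
                               miscall_rate = lib$config$miscall_rate,
                               frac_high_err = lib$config$frac_high_err,
                               reads_per_barcode = lib$config$reads_per_barcode) {
  stopifnot(inherits(lib, "sim_library"))
  if (nrow(lib$barcode_map) == 0) stop("barcode map is empty")
  if (miscall_rate < 0 || miscall_rate >= 1) stop("miscall_rate must be in [0, 1)")
  cfg <- lib$config
  set.seed(.substream(cfg$seed, 3L))

  map <- lib$barcode_map
  n_reads <- if (is.function(reads_per_barcode)) {
    reads_per_barcode(nrow(map))
  } else {
    1L + stats::rpois(nrow(map), reads_per_barcode)
  }
  if (any(n_reads < 1)) stop("every barcode needs at least one read")
  rec <- map[rep(seq_len(nrow(map)), n_reads), c("barcode", "codon_subs")]
  n <- nrow(rec)
  cds_chars <- strsplit(lib$cds, "")[[1]]

  call <- rec$codon_subs
  miscalled <- stats::runif(n) < miscall_rate
  if (any(miscalled)) {
    pos <- sample.int(length(cds_chars), sum(miscalled), replace = TRUE)
    ref <- cds_chars[pos]
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    extra <- paste0(pos, ref, ">", alt)
    call[miscalled] <- ifelse(call[miscalled] == "", extra,
                              paste(call[miscalled], extra, sep = ";"))
  }

  high <- stats::runif(n) < frac_high_err
  err_cds <- ifelse(high, 10^stats::runif(n, -3.9, -2.5),
                    10^stats::runif(n, -6, -4.1))
  err_bc <- ifelse(high, 10^stats::runif(n, -2.9, -1.5),
                   10^stats::runif(n, -6, -3.1))

  tibble::tibble(barcode = rec$barcode, variant_call = call,
                 err_cds = err_cds, err_bc = err_bc)
}
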