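# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: each re-derives its quantity from first principles so
# the implementation is checked by a second route.

# a small but fully featured simulation: enough synonymous/nonsense anchors
# for thresholds, modest depth for speed
small_config <- function(seed = 1, ...) {
  args <- list(L = 45, n_cells = 5e4, read_depth = 2e5, n_replicates = 2,
               barcodes_per_variant = 2, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# weighted mean by explicit loop
oracle_raw_score <- function(cells, fluor) {
  num <- 0
  den <- 0
  for (i in seq_along(cells)) {
    if (!is.na(cells[i]) && cells[i] > 0) {
      num <- num + cells[i] * fluor[i]
      den <- den + cells[i]
    }
  }
  if (den == 0) NA_real_ else num / den
}

# per-point tricube-weighted linear regression over the ns nearest points
# (no robustness iterations), window size ns = floor(f*n + 1e-7); when the
# weighted x spread is below 0.001 of the x range the local line is
# ill-conditioned and the fit degrades to the weighted mean
oracle_lowess <- function(x, y, fraction) {
  n <- length(x)
  ns <- max(min(floor(fraction * n + 1e-7), n), 2)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[ns]
    w <- rep(0, n)
    if (h > 0) {
      u <- d / h
      w[u < 1] <- (1 - u[u < 1]^3)^3
    } else {
      w[d == 0] <- 1
    }
    w <- w / sum(w)
    xbar <- sum(w * x)
    ybar <- sum(w * y)
    cxx <- sum(w * (x - xbar)^2)
    if (sqrt(cxx) > 0.001 * diff(range(x))) {
      ybar + sum(w * (x - xbar) * y) / cxx * (x[i] - xbar)
    } else {
      ybar
    }
  }, numeric(1))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_enum <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  }
  u_obs <- u_of(seq_len(n_a))
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# brute-force BH step-up: largest k with p_(k) <= k*alpha/m
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (j in seq_len(m)) if (ps[j] <= j * alpha / m) k <- j
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# AUROC by explicit pair counting, ties worth one half
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# minimal hand-built long-read record table
records_tbl <- function(barcode, call, err_cds = 0, err_bc = 0) {
  tibble::tibble(barcode = barcode, variant_call = call,
                 err_cds = err_cds, err_bc = err_bc)
}

# a one-variant library for distributional sort checks
single_barcode_library <- function(ddg_var = 0, config = small_config()) {
  truth <- tibble::tibble(
    variant = "A1V", position = 1L, wt_aa = "A", mut_aa = "V",
    vclass = "missense", ddg_var = ddg_var, rescuable = TRUE
  )
  map <- tibble::tibble(
    barcode = "ACGTACGTACGTACGT", variant = "A1V", position = 1L,
    wt_aa = "A", mut_aa = "V", vclass = "missense",
    codon_subs = "2C>T", n_nt_changes = 1L
  )
  structure(list(truth = truth, barcode_map = map,
                 cds = "GCT", config = config),
            class = "sim_library")
}

# toy PDB with a protein residue and a two-atom ligand at known coordinates
write_toy_pdb <- function(path) {
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1, 10, 0, 0, 0),
    sprintf("ATOM  %5d  CB  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            2, 10, 0, 0, -8),
    sprintf("ATOM  %5d  H   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           H",
            3, 10, 3, 3.5, 0),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            4, 11, 20, 20, 20),
    sprintf("HETATM%5d  C1  LIG B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            5, 1, 3, 4, 0),
    sprintf("HETATM%5d  C2  LIG B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            6, 1, 10, 0, 0),
    "END"
  )
  writeLines(lines, path)
  path
}
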