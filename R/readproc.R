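# Barcode-variant map construction: quality filters, strict per-barcode
# consensus, support-based retention, and codon-frame translation of
# nucleotide substitution calls against a reference CDS.

#' Quality-filter long-read records
#'
#' Keeps records whose estimated error rates fall at or below the thresholds
#' for both the coding sequence and the barcode. Order-preserving.
#'
#' @param records tibble with columns `barcode`, `variant_call`, `err_cds`,
#'   `err_bc` (as from [simulate_longreads()] or a converted consensus file).
#' @param max_err_cds,max_err_bc maximum tolerated estimated error rates.
#' @return the filtered tibble.
#' @export
filter_longreads <- function(records, max_err_cds = 1e-4, max_err_bc = 1e-3) {
  stopifnot(max_err_cds > 0, max_err_cds < 1, max_err_bc > 0, max_err_bc < 1)
  dplyr::filter(records, .data$err_cds <= max_err_cds,
                .data$err_bc <= max_err_bc)
}

# canonical form of a substitution list: sorted by nucleotide position
.normalize_call <- function(call) {
  vapply(strsplit(ifelse(is.na(call), "", call), ";", fixed = TRUE),
         function(s) {
           s <- s[nzchar(s)]
           if (length(s) == 0) return("")
           pos <- as.integer(stringr::str_extract(s, "^\\d+"))
           paste(unique(s[order(pos, s)]), collapse = ";")
         }, character(1))
}

#' Call a per-barcode consensus variant
#'
#' Groups records by barcode and requires strict agreement: if every record
#' carries the same substitution set (compared as sets), the consensus is
#' that call with support equal to the group size; any disagreement marks
#' the barcode as conflicted.
#'
#' @param records quality-filtered long-read records.
#' @return tibble with columns `barcode`, `variant_call`, `support`,
#'   `n_nt_changes`, `conflicted`.
#' @export
consensus_by_barcode <- function(records) {
  records %>%
    dplyr::mutate(call = .normalize_call(.data$variant_call)) %>%
    dplyr::summarise(
      support = dplyr::n(),
      conflicted = dplyr::n_distinct(.data$call) > 1,
      variant_call = dplyr::first(.data$call),
      .by = "barcode"
    ) %>%
    dplyr::mutate(
      variant_call = dplyr::if_else(.data$conflicted, NA_character_,
                                    .data$variant_call),
      n_nt_changes = dplyr::if_else(
        is.na(.data$variant_call) | .data$variant_call == "", 0L,
        stringr::str_count(.data$variant_call, ";") + 1L
      )
    ) %>%
    dplyr::select("barcode", "variant_call", "support", "n_nt_changes",
                  "conflicted")
}

#' Retain barcodes by consensus support
#'
#' Keeps non-conflicted barcodes with consensus support >= 2, plus barcodes
#' with support 1 whose variant exhibits multiple nucleotide changes (a
#' single long read is trusted only when the call could not arise from one
#' sequencing miscall). Wild-type (empty-call) barcodes require support >= 2.
#' Idempotent.
#'
#' @param map tibble from [consensus_by_barcode()].
#' @return the retained subset.
#' @export
retain_barcodes <- function(map) {
  dplyr::filter(
    map,
    !.data$conflicted,
    .data$support >= 2 | (.data$support == 1 & .data$n_nt_changes >= 2)
  )
}

#' Translate consensus nucleotide calls to protein variants
#'
#' Applies each barcode's substitution set to the reference CDS in codon
#' frame, translates with the standard genetic code, and reports the
#' amino-acid level variant. Substitutions beyond the CDS are ignored for
#' variant identity (but still count toward `n_nt_changes`). A call that
#' changes no amino acid is classed `synonymous` (or `wildtype` when the
#' call is empty); calls changing more than one residue are classed `multi`.
#'
#' @param map retained consensus map (tibble with `barcode`, `variant_call`,
#'   `support`, `n_nt_changes`).
#' @param cds reference coding sequence (a single string, length a multiple
#'   of 3), e.g. the `cds` element of a `sim_library` or the first record of
#'   a FASTA read with `Biostrings::readDNAStringSet()`.
#' @return tibble with columns `barcode`, `variant`, `position`, `wt_aa`,
#'   `mut_aa`, `vclass`, `support`, `n_nt_changes`.
#' @export
translate_calls <- function(map, cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  cds_chars <- strsplit(cds, "")[[1]]
  wt_codons <- apply(matrix(cds_chars, nrow = 3), 2, paste, collapse = "")
  wt_chars <- unname(GENETIC_CODE_TABLE[wt_codons])
  if (any(is.na(wt_chars))) stop("CDS contains non-ACGT characters")

  # only substituted codons can change: mutate and translate those alone
  calls <- unique(map$variant_call)
  per_call <- purrr::map(calls, function(cl) {
    if (is.na(cl) || cl == "") {
      return(tibble::tibble(variant_call = cl, variant = "WT",
                            position = NA_integer_, wt_aa = NA_character_,
                            mut_aa = NA_character_, vclass = "wildtype"))
    }
    subs <- strsplit(cl, ";", fixed = TRUE)[[1]]
    m <- stringr::str_match(subs, "^(\\d+)([ACGT])>([ACGT])$")
    if (any(is.na(m[, 1]))) stop("malformed substitution in call: ", cl)
    pos <- as.integer(m[, 2])
    in_cds <- pos >= 1 & pos <= length(cds_chars)
    pos <- pos[in_cds]
    alt <- m[in_cds, 4]
    if (length(pos) == 0) {
      return(tibble::tibble(variant_call = cl, variant = "WT",
                            position = NA_integer_, wt_aa = NA_character_,
                            mut_aa = NA_character_, vclass = "wildtype"))
    }
    touched <- sort(unique((pos - 1L) %/% 3L + 1L))
    mut_aa_at <- vapply(touched, function(cp) {
      codon <- strsplit(wt_codons[cp], "")[[1]]
      within <- pos - (cp - 1L) * 3L
      hit <- within >= 1 & within <= 3
      codon[within[hit]] <- alt[hit]
      unname(GENETIC_CODE_TABLE[paste(codon, collapse = "")])
    }, character(1))
    diffs <- touched[mut_aa_at != wt_chars[touched]]
    if (length(diffs) == 0) {
      p <- touched[1]
      return(tibble::tibble(variant_call = cl,
                            variant = format_variant_key(wt_chars[p], p, "="),
                            position = as.integer(p), wt_aa = wt_chars[p],
                            mut_aa = "=", vclass = "synonymous"))
    }
    if (length(diffs) > 1) {
      return(tibble::tibble(variant_call = cl, variant = "multi",
                            position = NA_integer_, wt_aa = NA_character_,
                            mut_aa = NA_character_, vclass = "multi"))
    }
    p <- diffs
    mut_aa <- mut_aa_at[match(p, touched)]
    tibble::tibble(variant_call = cl,
                   variant = format_variant_key(wt_chars[p], p, mut_aa),
                   position = as.integer(p), wt_aa = wt_chars[p],
                   mut_aa = mut_aa,
                   vclass = variant_class(wt_chars[p], mut_aa))
  })
  map %>%
    dplyr::left_join(dplyr::bind_rows(per_call), by = "variant_call") %>%
    dplyr::select("barcode", "variant", "position", "wt_aa", "mut_aa",
                  "vclass", "support", "n_nt_changes")
}

#' Build a barcode-variant map from long-read records
#'
#' End-to-end map construction: quality filtering, strict consensus,
#' support-based retention and translation. Barcodes whose consensus changes
#' more than one residue (`vclass == "multi"`) are dropped, since the
#' library is single-substitution by construction.
#'
#' @inheritParams filter_longreads
#' @inheritParams translate_calls
#' @return a barcode-variant map tibble (see [translate_calls()]).
#' @export
build_barcode_map <- function(records, cds,
                              max_err_cds = 1e-4, max_err_bc = 1e-3) {
  records %>%
    filter_longreads(max_err_cds, max_err_bc) %>%
    consensus_by_barcode() %>%
    retain_barcodes() %>%
    translate_calls(cds) %>%
    dplyr::filter(.data$vclass != "multi")
}
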