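#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order. Used by the library generator and
#' by annotation helpers that loop over mutant residues.
#' @export
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Format a variant key
#'
#' Variants are keyed as `"A84P"` (missense), `"W71*"` (nonsense),
#' `"L62="` (synonymous wild-type codon change) and `"WT"` (the unmutated
#' genotype). This single string is the join key used throughout the package.
#'
#' @param wt_aa wild-type residue, one-letter code.
#' @param position 1-based residue index.
#' @param mut_aa mutant residue, one-letter code, `"*"` for a stop or `"="`
#'   for a synonymous change.
#' @return character vector of variant keys.
#' @export
#' @examples
#' format_variant_key(c("A", "W"), c(84, 71), c("P", "*"))
format_variant_key <- function(wt_aa, position, mut_aa) {
  dplyr::if_else(
    is.na(position),
    "WT",
    paste0(wt_aa, position, mut_aa)
  )
}

#' Parse variant keys into components
#'
#' Inverse of [format_variant_key()]. The key `"WT"` parses to `NA`
#' components with class `"wildtype"`.
#'
#' @param key character vector of variant keys.
#' @return a tibble with columns `variant`, `position`, `wt_aa`, `mut_aa`,
#'   `vclass`.
#' @export
parse_variant_key <- function(key) {
  m <- stringr::str_match(key, "^([A-Z])(\\d+)([A-Z*=])$")
  bad <- is.na(m[, 1]) & key != "WT"
  if (any(bad)) {
    stop("malformed variant key(s): ", paste(utils::head(key[bad], 3), collapse = ", "))
  }
  tibble::tibble(
    variant = key,
    position = as.integer(m[, 3]),
    wt_aa = m[, 2],
    mut_aa = m[, 4],
    vclass = variant_class(m[, 2], m[, 4], key)
  )
}

variant_class <- function(wt_aa, mut_aa, key = NULL) {
  is_wt <- if (is.null(key)) rep(FALSE, length(mut_aa)) else !is.na(key) & key == "WT"
  dplyr::case_when(
    is_wt ~ "wildtype",
    mut_aa == "*" ~ "nonsense",
    mut_aa == "=" ~ "synonymous",
    TRUE ~ "missense"
  )
}
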