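# Codon-state machinery shared by the whole package. All likelihood code
# works on the 61 sense codons of the standard genetic code; stop codons
# (TAA, TAG, TGA) are never substitution states.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_env <- new.env(parent = emptyenv())

#' Sense-codon state table
#'
#' Returns the ordered vector of the 61 sense codons of the standard
#' genetic code, the alphabet over which all codon substitution models in
#' this package are defined.
#'
#' @return Character vector of length 61 (alphabetical codon order).
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$sense)) {
    nt <- c("A", "C", "G", "T")
    all64 <- apply(expand.grid(nt, nt, nt, stringsAsFactors = FALSE)[, 3:1],
                   1L, paste0, collapse = "")
    all64 <- sort(all64)
    .codon_env$sense <- setdiff(all64, STOP_CODONS)
  }
  .codon_env$sense
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of codons (may contain `NA`).
#' @return Character vector of one-letter amino acids; `NA` propagates,
#'   stops translate to `"*"`.
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codons])
  out[is.na(codons)] <- NA_character_
  out
}

# amino acid of each sense codon, in sense_codons() order
sense_codon_aa <- function() {
  if (is.null(.codon_env$aa)) .codon_env$aa <- translate_codons(sense_codons())
  .codon_env$aa
}

# Precomputed single-nucleotide-neighbour structure of the 61x61 state
# space: for each ordered pair differing at exactly one position, whether
# the change is a transition and whether it is synonymous.
codon_pair_table <- function() {
  if (!is.null(.codon_env$pairs)) return(.codon_env$pairs)
  cod <- sense_codons()
  n <- length(cod)
  mat <- do.call(rbind, strsplit(cod, ""))
  aa <- sense_codon_aa()
  is_transition <- function(a, b) {
    (a %in% c("A", "G") & b %in% c("A", "G")) |
      (a %in% c("C", "T") & b %in% c("C", "T"))
  }
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(mat[, p], mat[, p], "!=")
  single <- ndiff == 1L
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    diff_p <- outer(mat[, p], mat[, p], "!=")
    ts_p <- outer(mat[, p], mat[, p], is_transition)
    ts <- ts | (single & diff_p & ts_p)
  }
  syn <- outer(aa, aa, "==")
  .codon_env$pairs <- list(single = single, transition = ts, synonymous = syn)
  .codon_env$pairs
}

#' Amino-acid chemical property groups
#'
#' Default partition of the 20 amino acids into chemical-property groups
#' used for conservative-replacement calls in [classify_columns()].
#' Glycine and proline are kept as singleton groups: both are structurally
#' exceptional (backbone flexibility and rigidity respectively), which
#' matters in proline-rich extracellular matrix proteins.
#'
#' @return Named list of character vectors partitioning the 20 residues.
#' @export
aa_property_groups <- function() {
  list(
    aliphatic = c("A", "V", "L", "I", "M", "C"),
    aromatic  = c("F", "W", "Y"),
    basic     = c("K", "R", "H"),
    acidic    = c("D", "E"),
    polar     = c("S", "T", "N", "Q"),
    glycine   = "G",
    proline   = "P"
  )
}
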