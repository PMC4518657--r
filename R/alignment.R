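# Codon alignment container and FASTA I/O.
#
# A codon_alignment is a taxa x codon-column character matrix whose cells
# are sense codons or NA (the MISSING state: gaps, ambiguity codes,
# frameshift marks, masked stops). Coordinates are 1-based codon columns.

#' Construct a codon alignment
#'
#' @param codons Character matrix (taxa in rows, codon columns), cells are
#'   3-letter codons or `NA` for missing/gap. Row names are taxon names.
#' @param reference Optional taxon name used as the coordinate reference.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(codons, reference = NULL) {
  stopifnot(is.matrix(codons), is.character(codons))
  taxa <- rownames(codons)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("all rows must carry non-empty taxon names")
  if (anyDuplicated(taxa)) stop("duplicate taxon names: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  vals <- codons[!is.na(codons)]
  bad <- setdiff(unique(vals), sense_codons())
  if (length(bad))
    stop("non-sense-codon states in alignment: ", paste(bad, collapse = ", "))
  if (!is.null(reference) && !reference %in% taxa)
    stop("reference taxon '", reference, "' not in alignment")
  structure(list(codons = codons, taxa = taxa,
                 length_codons = ncol(codons), reference = reference),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", x$length_codons, "codons\n")
  if (!is.null(x$reference)) cat("reference:", x$reference, "\n")
  miss <- mean(is.na(x$codons))
  cat(sprintf("missing/gap codons: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$codons)

# split nucleotide strings into codon triplets; no validation here
split_codons <- function(seqs) {
  t(vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    apply(matrix(chars, nrow = 3), 2L, paste0, collapse = "")
  }, character(nchar(seqs[[1]]) / 3)))
}

#' Read a codon alignment from FASTA
#'
#' Reads an in-frame nucleotide alignment and converts it to codon states.
#' Any codon containing a non-ACGT character (gap `-`, `N`, IUPAC
#' ambiguity, frameshift marks such as `!`) becomes the MISSING state.
#' In-frame stop codons are handled per `stop_policy`: `"reject"` raises
#' an error (functional-sequence alignments must be stop-free), `"mask"`
#' converts them to MISSING (appropriate when pseudogenes are retained).
#'
#' @param path FASTA file of equal-length nucleotide sequences whose
#'   length is divisible by 3.
#' @param stop_policy `"reject"` (default) or `"mask"`.
#' @param reference Optional reference taxon name.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path, stop_policy = c("reject", "mask"),
                                 reference = NULL) {
  stop_policy <- match.arg(stop_policy)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  codon_alignment_from_strings(seqs, stop_policy = stop_policy,
                               reference = reference)
}

#' Build a codon alignment from named nucleotide strings
#'
#' Same conversion rules as [read_codon_alignment()]; exposed so that
#' simulated or in-memory sequences can enter the analysis path without a
#' file round-trip.
#'
#' @inheritParams read_codon_alignment
#' @param seqs Named character vector of aligned nucleotide sequences.
#' @return A [codon_alignment()].
#' @export
codon_alignment_from_strings <- function(seqs, stop_policy = c("reject", "mask"),
                                         reference = NULL) {
  stop_policy <- match.arg(stop_policy)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon names in input")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences differ in length (", paste(unique(lens), collapse = ", "), ")")
  if (lens[1] %% 3L != 0L)
    stop("alignment length ", lens[1], " is not divisible by 3")
  cod <- split_codons(seqs)
  rownames(cod) <- names(seqs)
  not_acgt <- grepl("[^ACGT]", cod)
  cod[not_acgt] <- NA_character_
  is_stop <- !is.na(cod) & cod %in% STOP_CODONS
  if (any(is_stop)) {
    if (stop_policy == "reject") {
      idx <- which(is_stop, arr.ind = TRUE)[1L, ]
      stop("in-frame stop codon at taxon '", rownames(cod)[idx[1]],
           "', codon ", idx[2], " (use stop_policy = \"mask\" to retain)")
    }
    cod[is_stop] <- NA_character_
  }
  codon_alignment(cod, reference = reference)
}

#' Write a codon alignment to FASTA
#'
#' MISSING codons are written as `---`.
#'
#' @param aln A [codon_alignment()].
#' @param path Output file.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  cod <- aln$codons
  cod[is.na(cod)] <- "---"
  seqs <- apply(cod, 1L, paste0, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Project an alignment onto a reference sequence
#'
#' Drops every codon column in which the reference taxon is missing or
#' gapped, so that the result is in the reference's own ungapped codon
#' coordinates. If the reference ends with a stop codon the final column
#' would already have been masked or rejected on read; a trailing column
#' that is MISSING in the reference is dropped like any other.
#'
#' @param aln A [codon_alignment()].
#' @param ref Reference taxon name; defaults to `aln$reference`.
#' @return A [codon_alignment()] with `reference` set to `ref`.
#' @export
project_to_reference <- function(aln, ref = aln$reference) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(ref)) stop("no reference taxon given")
  if (!ref %in% aln$taxa) stop("reference taxon '", ref, "' not in alignment")
  keep <- !is.na(aln$codons[ref, ])
  codon_alignment(aln$codons[, keep, drop = FALSE], reference = ref)
}

#' Amino-acid view of a codon alignment
#'
#' @param aln A [codon_alignment()].
#' @return Character matrix of one-letter residues (`NA` for missing).
#' @export
as_aa_matrix <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  aa <- translate_codons(aln$codons)
  matrix(aa, nrow = nrow(aln$codons), dimnames = dimnames(aln$codons))
}

# integer state encoding used by the likelihood core: 1..61 in
# sense_codons() order, NA for missing; rows reordered to `taxa` if given
codon_state_matrix <- function(aln, taxa = NULL) {
  cod <- aln$codons
  if (!is.null(taxa)) {
    if (!setequal(taxa, rownames(cod)))
      stop("tree tip labels do not match alignment taxa")
    cod <- cod[taxa, , drop = FALSE]
  }
  m <- matrix(match(cod, sense_codons()), nrow = nrow(cod),
              dimnames = dimnames(cod))
  m
}
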