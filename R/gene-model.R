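# Gene models: exon structure over a genomic sequence, with spliced CDS
# and UTRs. Coordinates are 1-based, inclusive, forward strand.

#' Construct a gene model
#'
#' @param name Gene name.
#' @param genomic Genomic (pre-mRNA orientation) nucleotide sequence.
#' @param exons Data frame with columns `exon_id`, `start`, `end`
#'   (1-based inclusive, non-overlapping, in 5'->3' order).
#' @param cds_start,cds_end Genomic coordinates of the first base of the
#'   start codon and the last base of the stop codon.
#' @return Object of class `gene_model` with spliced `mrna`, `cds`
#'   (stop codon included), `utr5`, `utr3` and `protein` fields.
#' @export
gene_model <- function(name, genomic, exons, cds_start, cds_end) {
  genomic <- toupper(genomic)
  glen <- nchar(genomic)
  stopifnot(is.data.frame(exons),
            all(c("exon_id", "start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start < 1 | exons$end > glen))
    stop("exon coordinates outside genomic sequence (length ", glen, ")")
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap")
  if (cds_start < 1 || cds_end > glen || cds_end <= cds_start)
    stop("CDS span outside genomic sequence")

  # genomic -> spliced coordinate map
  gpos <- unlist(mapply(seq, exons$start, exons$end, SIMPLIFY = FALSE))
  mrna <- paste0(substring(genomic, gpos, gpos), collapse = "")
  sp_start <- match(cds_start, gpos)
  sp_end <- match(cds_end, gpos)
  if (is.na(sp_start) || is.na(sp_end))
    stop("CDS boundaries do not fall inside exons")
  cds <- substr(mrna, sp_start, sp_end)
  if (nchar(cds) %% 3L != 0L)
    stop("spliced CDS length ", nchar(cds), " not divisible by 3")
  last_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
  has_stop <- last_codon %in% STOP_CODONS
  coding <- if (has_stop) substr(cds, 1L, nchar(cds) - 3L) else cds
  codons <- substring(coding, seq(1, nchar(coding), 3), seq(3, nchar(coding), 3))
  protein <- paste0(translate_codons(codons), collapse = "")
  structure(list(
    name = name, genomic = genomic, exons = exons,
    cds_start = cds_start, cds_end = cds_end,
    mrna = mrna, cds = cds,
    utr5 = substr(mrna, 1L, sp_start - 1L),
    utr3 = if (sp_end < nchar(mrna)) substr(mrna, sp_end + 1L, nchar(mrna)) else "",
    stop_codon = if (has_stop) last_codon else NA_character_,
    protein = protein
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$name, "-", nrow(x$exons), "exons,",
      nchar(x$cds), "nt CDS,", nchar(x$protein), "aa protein\n")
  cat("5'UTR:", nchar(x$utr5), "nt  3'UTR:", nchar(x$utr3), "nt\n")
  invisible(x)
}

#' Read a gene model from annotation + genomic FASTA
#'
#' The annotation is a tab-delimited table with header columns
#' `gene`, `exon_id`, `start`, `end` (1-based inclusive), plus one row
#' with `exon_id == "CDS"` giving the CDS span. The FASTA holds the
#' genomic sequence, forward strand.
#'
#' @param annotation_path Tab-delimited annotation file.
#' @param fasta_path Genomic FASTA (first record used).
#' @return A [gene_model()].
#' @export
read_gene_model <- function(annotation_path, fasta_path) {
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("gene", "exon_id", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  genomic <- as.character(Biostrings::readBStringSet(fasta_path))[[1]]
  cds_row <- ann$exon_id == "CDS"
  if (sum(cds_row) != 1L) stop("annotation needs exactly one CDS row")
  gene_model(name = ann$gene[1], genomic = genomic,
             exons = ann[!cds_row, c("exon_id", "start", "end")],
             cds_start = ann$start[cds_row], cds_end = ann$end[cds_row])
}

#' Write the annotation table of a gene model
#'
#' @param gm A [gene_model()].
#' @param path Output TSV path.
#' @export
write_gene_annotation <- function(gm, path) {
  tab <- rbind(
    data.frame(gene = gm$name, exon_id = gm$exons$exon_id,
               start = gm$exons$start, end = gm$exons$end),
    data.frame(gene = gm$name, exon_id = "CDS",
               start = gm$cds_start, end = gm$cds_end))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
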