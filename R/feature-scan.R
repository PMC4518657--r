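# Gene-feature scanners: Kozak translation-initiation contexts,
# polyadenylation hexamers with ancestral-presence parsimony, tandem
# exon-duplication detection, and pseudogene diagnostics.

#' Scan a 5' sequence for translation initiation sites
#'
#' Reports every ATG with its Kozak context: the bases at positions -3
#' (three bases upstream of the A) and +4 (the base immediately after
#' the G). The context is `strong` iff both are purines (A/G); a
#' missing upstream base leaves the context undetermined and the class
#' weak. When `cds_end` is supplied, `open_frame` records whether
#' translation from the ATG reaches that position without an in-frame
#' premature stop, and the 5'-most open-frame ATG is flagged `primary`
#' (scanning 5' to 3', the first usable start is taken as the
#' functional one).
#'
#' @param five_prime_seq Nucleotide sequence containing the candidate
#'   starts (mRNA orientation).
#' @param cds_end 1-based position of the last base of the stop codon
#'   (or of the annotated CDS end) within `five_prime_seq`'s coordinate
#'   system; `NA` skips the open-frame check.
#' @return Data frame: `position`, `minus3`, `plus4`, `context`
#'   (`strong`/`weak`), `open_frame`, `primary`.
#' @export
scan_tis <- function(five_prime_seq, cds_end = NA) {
  s <- toupper(five_prime_seq)
  pos <- as.integer(gregexpr("ATG", s)[[1]])
  if (length(pos) == 1L && pos == -1L)
    return(data.frame(position = integer(0), minus3 = character(0),
                      plus4 = character(0), context = character(0),
                      open_frame = logical(0), primary = logical(0)))
  minus3 <- ifelse(pos - 3 >= 1, substring(s, pos - 3, pos - 3),
                   NA_character_)
  plus4 <- ifelse(pos + 3 <= nchar(s), substring(s, pos + 3, pos + 3),
                  NA_character_)
  purine <- function(b) !is.na(b) & b %in% c("A", "G")
  context <- ifelse(purine(minus3) & purine(plus4), "strong", "weak")
  open_frame <- rep(NA, length(pos))
  if (!is.na(cds_end)) {
    open_frame <- vapply(pos, function(p) {
      if (cds_end < p + 2) return(FALSE)
      stretch <- substr(s, p, cds_end)
      n_full <- (nchar(stretch) %/% 3) * 3
      codons <- substring(stretch, seq(1, n_full - 2, 3), seq(3, n_full, 3))
      n_cod <- length(codons)
      internal_stops <- codons[-n_cod] %in% STOP_CODONS
      !any(internal_stops)
    }, logical(1))
  }
  primary <- rep(FALSE, length(pos))
  usable <- if (all(is.na(open_frame))) seq_along(pos) else which(open_frame)
  if (length(usable)) primary[usable[1]] <- TRUE
  data.frame(position = pos, minus3 = minus3, plus4 = plus4,
             context = context, open_frame = open_frame, primary = primary)
}

#' Scan a 3' UTR for polyadenylation signals
#'
#' Finds all occurrences of the canonical hexamer `AATAAA` and the
#' common variant `ATTAAA`. Position 1 is the first base after the stop
#' codon; spans are 1-based inclusive (`end = start + 5`). Overlapping
#' hits of the two different motifs are both reported; overlapping hits
#' of the same motif are all reported too (self-overlap of these
#' hexamers is only possible for degenerate runs). Signals are numbered
#' PS1, PS2, ... in ascending start order.
#'
#' @param three_prime_utr UTR sequence, 5' to 3', starting immediately
#'   after the stop codon.
#' @return Data frame: `ps` (index label), `motif`, `start`, `end`.
#' @export
scan_polya <- function(three_prime_utr) {
  s <- toupper(three_prime_utr)
  hits <- do.call(rbind, lapply(c("AATAAA", "ATTAAA"), function(m) {
    p <- as.integer(gregexpr(m, s, fixed = TRUE)[[1]])
    if (length(p) == 1L && p == -1L) return(NULL)
    data.frame(motif = m, start = p, end = p + 5L)
  }))
  if (is.null(hits))
    return(data.frame(ps = character(0), motif = character(0),
                      start = integer(0), end = integer(0)))
  hits <- hits[order(hits$start, hits$motif), ]
  data.frame(ps = paste0("PS", seq_len(nrow(hits))),
             motif = hits$motif, start = hits$start, end = hits$end,
             row.names = NULL)
}

# --- Fitch parsimony -------------------------------------------------------

# Two-pass Fitch on binary characters (columns of tip_states, values 0/1,
# NA = missing). Trees should be binary; polytomies are folded pairwise.
# Returns final state sets per internal node ("0", "1", "ambiguous") and
# the parsimony score per character.
fitch_parsimony <- function(tree, tip_states) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(dim(tip_states))) tip_states <- matrix(tip_states, ncol = 1)
  ntip <- length(tree$tip.label)
  if (nrow(tip_states) != ntip) stop("tip state rows must match tree tips")
  if (!is.null(rownames(tip_states))) {
    if (!setequal(rownames(tip_states), tree$tip.label))
      stop("tip state names do not match tree tip labels")
    tip_states <- tip_states[tree$tip.label, , drop = FALSE]
  }
  nch <- ncol(tip_states)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_node <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1]

  # bitmask sets: 1 = {0}, 2 = {1}, 3 = {0,1}
  D <- matrix(0L, n_node, nch)
  D[seq_len(ntip), ] <- ifelse(is.na(tip_states), 3L, tip_states + 1L)
  by_union <- matrix(FALSE, n_node, nch)
  score <- integer(nch)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (all(D[par, ] == 0L)) { D[par, ] <- D[ch, ]; next }
    inter <- bitwAnd(D[par, ], D[ch, ])
    uni <- bitwOr(D[par, ], D[ch, ])
    use_union <- inter == 0L
    score <- score + use_union
    by_union[par, ] <- by_union[par, ] | use_union
    D[par, ] <- ifelse(use_union, uni, inter)
  }

  # uppass: final sets
  FF <- matrix(0L, n_node, nch)
  FF[root, ] <- D[root, ]
  child_union <- matrix(0L, n_node, nch)
  for (v in as.integer(names(kids)))
    for (ch in kids[[as.character(v)]])
      child_union[v, ] <- bitwOr(child_union[v, ], D[ch, ])
  for (e in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[e, 1]; v <- tr$edge[e, 2]
    if (v <= ntip) next
    case1 <- bitwAnd(D[v, ], FF[par, ]) == FF[par, ]
    FF[v, ] <- ifelse(case1, FF[par, ],
                ifelse(by_union[v, ], bitwOr(D[v, ], FF[par, ]),
                       bitwOr(D[v, ], bitwAnd(FF[par, ], child_union[v, ]))))
  }
  internal <- (ntip + 1L):n_node
  states <- matrix(c("0", "1", "ambiguous")[FF[internal, , drop = FALSE]],
                   nrow = length(internal),
                   dimnames = list(paste0("node_", internal),
                                   colnames(tip_states)))
  list(states = states, score = score, root = states[paste0("node_", root), ])
}

#' Ancestral presence of binary features by Fitch parsimony
#'
#' Reconstructs presence/absence of each feature (column of the
#' presence matrix) at every internal node under Fitch parsimony.
#' Ties (nodes where both states occur in equally parsimonious
#' reconstructions) are reported as `"ambiguous"`, not guessed.
#'
#' @param presence_matrix Logical species x feature matrix with species
#'   row names matching the tree's tip labels.
#' @param tree Rooted [ape::phylo] tree.
#' @return List with `node_states` (internal-node x feature character
#'   matrix of `"present"`, `"absent"`, `"ambiguous"`), `root` (the
#'   root's row) and `score` (minimum changes per feature).
#' @export
ancestral_presence <- function(presence_matrix, tree) {
  if (is.null(rownames(presence_matrix)))
    stop("presence matrix needs species row names")
  miss <- setdiff(tree$tip.label, rownames(presence_matrix))
  if (length(miss) || !setequal(rownames(presence_matrix), tree$tip.label))
    stop("species do not match tree tips")
  fp <- fitch_parsimony(tree, ifelse(presence_matrix, 1L, 0L))
  relab <- function(x) ifelse(x == "1", "present",
                       ifelse(x == "0", "absent", "ambiguous"))
  states <- fp$states
  states[] <- relab(states)
  ntip <- length(tree$tip.label)
  root_name <- paste0("node_", ntip + 1L)
  list(node_states = states, root = states[root_name, ], score = fp$score)
}

# --- exon duplication ------------------------------------------------------

#' Detect tandem exon duplications in an intronic region
#'
#' Slides an ungapped window of the template exon's length along the
#' intron, computes percent identity at every offset, and greedily
#' selects non-overlapping hits at or above `min_identity` in
#' descending identity order (ties by position). Each hit carries a
#' splice-context flag: `AG` immediately upstream and `GT` immediately
#' downstream of the hit, the minimal requirement for the copy to be
#' spliceable as an exon.
#'
#' @param intron_seq Intron (search space) nucleotide sequence.
#' @param template_exon Template exon sequence (>= 10 nt).
#' @param min_identity Identity threshold in `[0, 1]` (default 0.8).
#' @return Data frame: `start`, `end`, `identity`, `length`,
#'   `splice_ag_upstream`, `splice_gt_downstream`.
#' @export
detect_exon_duplications <- function(intron_seq, template_exon,
                                     min_identity = 0.8) {
  s <- toupper(intron_seq)
  tmpl <- strsplit(toupper(template_exon), "")[[1]]
  L <- length(tmpl)
  if (L < 10) stop("template exon shorter than 10 nt is unreliable")
  n <- nchar(s)
  if (L > n) stop("template longer than the searched intron")
  sv <- strsplit(s, "")[[1]]
  n_off <- n - L + 1L
  ident <- vapply(seq_len(n_off), function(o)
    sum(sv[o:(o + L - 1L)] == tmpl) / L, numeric(1))
  cand <- which(ident >= min_identity)
  cand <- cand[order(-ident[cand], cand)]
  taken <- logical(n)
  hits <- list()
  for (o in cand) {
    span <- o:(o + L - 1L)
    if (any(taken[span])) next
    taken[span] <- TRUE
    hits[[length(hits) + 1L]] <- o
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      identity = numeric(0), length = integer(0),
                      splice_ag_upstream = logical(0),
                      splice_gt_downstream = logical(0)))
  st <- sort(unlist(hits))
  data.frame(
    start = st, end = st + L - 1L, identity = ident[st], length = L,
    splice_ag_upstream = st - 2 >= 1 & substring(s, st - 2, st - 1) == "AG",
    splice_gt_downstream = st + L + 1 <= n & substring(s, st + L, st + L + 1) == "GT")
}

#' Pseudogene diagnostics for a coding sequence
#'
#' Screens an (ungapped) coding sequence for the two signatures of
#' pseudogenization visible in sequence alone: in-frame premature stop
#' codons and a length not divisible by 3 (frameshift relative to an
#' intact reading frame).
#'
#' @param seq Nucleotide coding sequence, start codon first.
#' @return List: `premature_stops` (codon indices), `frameshifted`
#'   (length %% 3 != 0), `pseudogene` (either signature present).
#' @export
pseudogene_diagnostics <- function(seq) {
  s <- toupper(gsub("-", "", seq))
  nfull <- (nchar(s) %/% 3) * 3
  codons <- if (nfull >= 3)
    substring(s, seq(1, nfull - 2, 3), seq(3, nfull, 3)) else character(0)
  internal <- utils::head(codons, -1L)
  stops <- which(internal %in% STOP_CODONS)
  frameshifted <- nchar(s) %% 3L != 0L
  list(premature_stops = stops, frameshifted = frameshifted,
       pseudogene = frameshifted || length(stops) > 0)
}
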