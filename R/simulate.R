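# Synthetic-data generators: Yule trees, codon alignments evolved under
# known site/branch dN/dS regimes (with an optional Gillespie mode whose
# event log supports substitution-count audits), pseudogenized lineages,
# and 13-exon gene fixtures with planted 5'/3' features. Every generator
# is a pure function of its arguments and the seed.

#' Simulate a Yule tree
#'
#' Pure-birth tree rescaled so that the root-to-tip height equals
#' `height` expected substitutions per codon.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth_rate Birth rate of the Yule process (default 1).
#' @param height Target tree height in expected substitutions per codon
#'   (default 2, a mammal-depth calibration for a fast-evolving
#'   protein-coding gene: ~220 My root-to-tip at near-neutral rates).
#' @param seed RNG seed.
#' @return Rooted binary [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_leaves, birth_rate = 1, height = 2,
                          seed = NULL) {
  if (n_leaves < 2) stop("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / depth)
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr
}

#' Simulate a codon alignment along a tree
#'
#' Each codon column draws its dN/dS class from the site-class model's
#' proportions (fixed along the whole tree, the site-model assumption);
#' the root codon is drawn from the stationary distribution and each
#' branch evolved under the class's generator. With `branch_spec` and
#' `branch_omegas`, branches use their ratio class's dN/dS instead (the
#' site model should then be single-class). The default transition-
#' probability sampler draws child states directly from P(t); the
#' Gillespie sampler simulates the jump chain and logs every
#' substitution event with its syn/nonsyn status.
#'
#' @param tree [ape::phylo] tree with branch lengths.
#' @param model A [site_class_model()].
#' @param n_codons Number of codon columns.
#' @param kappa Transition/transversion ratio (default 2).
#' @param pi Codon frequencies (default uniform over sense codons).
#' @param branch_spec Optional [branch_classes()].
#' @param branch_omegas Per-class dN/dS when `branch_spec` given.
#' @param method `"matrix"` (default) or `"gillespie"`.
#' @param seed RNG seed.
#' @return List: `alignment` (a [codon_alignment()]), `truth` (list with
#'   per-site `class` and `omega`, per-edge `omega`, the seed, and for
#'   the Gillespie sampler an `events` data frame of substitutions with
#'   `edge`, `site`, `from`, `to`, `synonymous`).
#' @export
simulate_codon_alignment <- function(tree, model, n_codons, kappa = 2,
                                     pi = NULL, branch_spec = NULL,
                                     branch_omegas = NULL,
                                     method = c("matrix", "gillespie"),
                                     seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"), n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  ns <- length(sense_codons())
  if (is.null(pi)) pi <- stats::setNames(rep(1 / ns, ns), sense_codons())
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  n_node <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1]

  site_class <- sample.int(length(model$props), n_codons, replace = TRUE,
                           prob = model$props)
  site_omega <- model$omegas[site_class]
  edge_cls <- if (!is.null(branch_spec))
    reorder_edge_attribute(tree, tr, as.integer(branch_spec)) else NULL
  if (!is.null(branch_spec) && is.null(branch_omegas))
    stop("branch_omegas required with branch_spec")

  # distinct generators needed
  omega_set <- if (is.null(branch_spec)) sort(unique(site_omega))
               else sort(unique(branch_omegas))
  gens <- lapply(omega_set, function(w) {
    Q <- build_rate_matrix(kappa, w, pi)
    list(Q = Q, dec = decompose_generator(Q, pi))
  })
  names(gens) <- as.character(omega_set)

  node_state <- matrix(NA_integer_, n_node, n_codons)
  node_state[root, ] <- sample.int(ns, n_codons, replace = TRUE, prob = pi)
  events <- list()

  for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    t_e <- tr$edge.length[e]
    parent_states <- node_state[par, ]
    child_states <- integer(n_codons)
    site_w <- if (is.null(branch_spec)) site_omega
              else rep(branch_omegas[edge_cls[e] + 1L], n_codons)
    for (w in unique(site_w)) {
      idx <- which(site_w == w)
      g <- gens[[as.character(w)]]
      if (method == "matrix") {
        P <- transition_matrix(g$dec, g$Q, t_e)
        for (x in unique(parent_states[idx])) {
          sel <- idx[parent_states[idx] == x]
          child_states[sel] <- sample.int(ns, length(sel), replace = TRUE,
                                          prob = P[x, ])
        }
      } else {
        for (s_i in idx) {
          res <- gillespie_branch(parent_states[s_i], g$Q, t_e)
          child_states[s_i] <- res$state
          if (length(res$from)) {
            pt <- codon_pair_table()
            events[[length(events) + 1L]] <- data.frame(
              edge = e, site = s_i, from = res$from, to = res$to,
              synonymous = pt$synonymous[cbind(res$from, res$to)])
          }
        }
      }
    }
    node_state[ch, ] <- child_states
  }

  codons <- sense_codons()
  mat <- matrix(codons[node_state[seq_len(ntip), ]], nrow = ntip,
                dimnames = list(tr$tip.label, NULL))
  truth <- list(site_class = site_class, site_omega = site_omega,
                edge_omega = if (is.null(branch_spec))
                  NULL else branch_omegas[edge_cls + 1L],
                kappa = kappa, seed = seed,
                events = if (length(events)) do.call(rbind, events) else NULL)
  list(alignment = codon_alignment(mat), truth = truth, tree = tr)
}

# jump-chain simulation of one site along one branch
gillespie_branch <- function(state, Q, t_total) {
  from <- integer(0); to <- integer(0)
  t <- 0
  repeat {
    rate <- -Q[state, state]
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t >= t_total) break
    probs <- Q[state, ]
    probs[state] <- 0
    nxt <- sample.int(length(probs), 1L, prob = probs)
    from <- c(from, state); to <- c(to, nxt)
    state <- nxt
  }
  list(state = state, from = from, to = to)
}

#' Pseudogenize selected sequences
#'
#' Injects the mutational signatures of pseudogenization into the named
#' lineages of a set of coding sequences: nonsense substitutions
#' (codon -> premature stop) at `stop_rate` per codon and 1-2 nt
#' insertions/deletions at `indel_rate` per codon. Other sequences are
#' returned untouched. Events are logged with positions so simulated
#' truth can be audited against the emitted sequences.
#'
#' @param seqs Named character vector of in-frame nucleotide sequences.
#' @param lineages Names of sequences to pseudogenize.
#' @param stop_rate Per-codon nonsense substitution probability.
#' @param indel_rate Per-codon indel probability.
#' @param seed RNG seed.
#' @return List: `seqs` (mutated vector, lengths may change) and
#'   `events` data frame (`taxon`, `type`, `codon`, `detail`).
#' @export
pseudogenize <- function(seqs, lineages, stop_rate = 0.02, indel_rate = 0.01,
                         seed = NULL) {
  if (stop_rate < 0 || indel_rate < 0) stop("rates must be >= 0")
  miss <- setdiff(lineages, names(seqs))
  if (length(miss)) stop("unknown lineages: ", paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  events <- list()
  out <- seqs
  for (tx in lineages) {
    s <- toupper(out[[tx]])
    n_cod <- nchar(s) %/% 3
    stop_hits <- which(stats::runif(n_cod) < stop_rate)
    chars <- strsplit(s, "")[[1]]
    for (cidx in stop_hits) {
      new_stop <- sample(STOP_CODONS, 1L)
      chars[(3 * cidx - 2):(3 * cidx)] <- strsplit(new_stop, "")[[1]]
      events[[length(events) + 1L]] <- data.frame(
        taxon = tx, type = "nonsense", codon = cidx, detail = new_stop)
    }
    indel_hits <- which(stats::runif(n_cod) < indel_rate)
    # apply indels right-to-left so earlier codon indices stay valid
    for (cidx in rev(indel_hits)) {
      len <- sample(1:2, 1L)
      at <- 3 * cidx - 2
      if (stats::runif(1) < 0.5) {
        ins <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
        chars <- append(chars, strsplit(ins, "")[[1]], after = at - 1L)
        detail <- paste0("+", ins)
      } else {
        del_to <- min(at + len - 1L, length(chars))
        detail <- paste0("-", paste0(chars[at:del_to], collapse = ""))
        chars <- chars[-(at:del_to)]
      }
      events[[length(events) + 1L]] <- data.frame(
        taxon = tx, type = "indel", codon = cidx, detail = detail)
    }
    out[[tx]] <- paste0(chars, collapse = "")
  }
  list(seqs = out,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(taxon = character(0), type = character(0),
                                codon = integer(0), detail = character(0)))
}

#' Build a gene fixture with planted 5'/3' features
#'
#' Emits a 13-exon gene model carrying configurable planted features:
#' ATG translation-initiation contexts in exons 1 and 2, polyadenylation
#' hexamers at requested 3'UTR offsets, and tandem 39-bp copies of
#' exon 7 in the exon 7 - exon 10 intron. The returned truth table
#' records every planted feature so scanner output can be compared
#' exactly.
#'
#' @param tis Character: `"weak1_strong2"` (weak-context ATG in exon 1
#'   plus strong-context ATG in exon 2, the common placental layout),
#'   `"exon2_only"` (single TIS in exon 2, the marsupial/monotreme
#'   layout) or `"extra_strong1"` (an additional upstream strong-context
#'   ATG in exon 1, the bovine layout).
#' @param polya_offsets Integer vector of 3'UTR start offsets (1 = first
#'   base after the stop codon) where `AATAAA`/`ATTAAA` hexamers are
#'   planted; motifs alternate starting with `ATTAAA` to mimic the
#'   PS1/PS4-variant pattern, unless `polya_motifs` is supplied.
#' @param polya_motifs Optional explicit motif per offset.
#' @param n_exon7_copies Number of 39-bp exon-7 copies planted in the
#'   exon 7 - exon 10 intron (default 2).
#' @param copy_identity Per-base identity of each planted copy to
#'   exon 7 (default 1).
#' @param utr3_length 3'UTR length in nt (default 553).
#' @param seed RNG seed.
#' @return List: `gene` (a [gene_model()]), `truth` (planted TIS table,
#'   polyA table, duplication table, seed).
#' @export
make_gene_fixture <- function(tis = c("weak1_strong2", "exon2_only",
                                      "extra_strong1"),
                              polya_offsets = c(106, 129, 189, 415, 536),
                              polya_motifs = NULL,
                              n_exon7_copies = 2, copy_identity = 1,
                              utr3_length = 553, seed = NULL) {
  tis <- match.arg(tis)
  if (!is.null(seed)) set.seed(seed)
  nt <- c("A", "C", "G", "T")
  rnt <- function(n) paste0(sample(nt, n, replace = TRUE), collapse = "")
  # random sequence with no ATG, no stop-forming risk handled later
  rnt_no_atg <- function(n) {
    repeat {
      s <- rnt(n)
      if (!grepl("ATG", s) && !grepl("AATAAA|ATTAAA", s)) return(s)
    }
  }

  if (is.null(polya_motifs)) {
    polya_motifs <- rep(c("ATTAAA", "AATAAA"), length.out = length(polya_offsets))
    if (length(polya_offsets) >= 2) # canonical pattern: variants at 1st, 4th
      polya_motifs <- ifelse(seq_along(polya_offsets) %in% c(1, 4),
                             "ATTAAA", "AATAAA")
  }
  if (length(polya_motifs) != length(polya_offsets))
    stop("polya_motifs must match polya_offsets")
  if (any(diff(sort(polya_offsets)) < 6))
    stop("planted polyadenylation signals overlap")

  # --- coding content: codons free of stops and internal ATG/motifs
  safe_codons <- setdiff(sense_codons(),
                         c("ATG", grep("^AT|TA$", sense_codons(), value = TRUE)))
  rcod <- function(n) paste0(sample(safe_codons, n, replace = TRUE),
                             collapse = "")

  # 13 exons; exon sizes loosely follow a real enamel-gene layout, with
  # exon 7 fixed at 39 nt and a long terminal exon
  exon_cds_len <- c(9, 51, 48, 45, 60, 165, 39, 39, 39, 45, 42, 48, 600)
  utr5_exon1 <- 60   # leading UTR inside exon 1
  tis_truth <- list()
  # Assembly: the mRNA is [utr5][CDS][utr3]; exon boundaries then cut the
  # genomic sequence. The CDS begins with ATG in exon 1 (or exon 2).
  cds_codons <- sum(exon_cds_len) / 3
  stopifnot(sum(exon_cds_len) %% 3 == 0)

  build_cds <- function() {
    body <- rcod(cds_codons - 2L)  # minus start codon and stop
    paste0("ATG", body, "TGA")
  }
  cds <- build_cds()

  # 5' UTR with the planted contexts
  if (tis == "exon2_only") {
    # ATG sits at the start of exon 2's CDS; exon 1 is untranslated
    utr5 <- paste0(rnt_no_atg(utr5_exon1 - 3), "ACC")  # strong -3 context
    tis_truth$exon2 <- list(context = "strong", position = utr5_exon1 + 1L)
    exon1_cds_len <- 0L
  } else if (tis == "weak1_strong2") {
    utr5 <- paste0(rnt_no_atg(utr5_exon1 - 3), "CCC")  # pyrimidine at -3
    tis_truth$exon1 <- list(context = "weak", position = utr5_exon1 + 1L)
    tis_truth$exon2 <- list(context = "strong",
                            position = utr5_exon1 + exon_cds_len[1] + 1L)
    exon1_cds_len <- exon_cds_len[1]
  } else {
    # bovine-like: upstream strong ATG within the UTR region of exon 1,
    # in frame with the downstream CDS (12 nt upstream of the main ATG)
    pre <- rnt_no_atg(utr5_exon1 - 3 - 12)
    utr5 <- paste0(pre, "ACC", "ATGGCTCCTCCC")
    tis_truth$extra_exon1 <- list(context = "strong",
                                  position = nchar(pre) + 4L)
    tis_truth$exon1 <- list(context = "weak", position = utr5_exon1 + 1L)
    exon1_cds_len <- exon_cds_len[1]
  }

  # ensure +4 contexts: first CDS base after exon-1 ATG is the next codon's
  # first base. Force them per layout:
  cds_chars <- strsplit(cds, "")[[1]]
  if (tis == "weak1_strong2") cds_chars[4] <- "C"  # pyrimidine +4 -> weak
  if (tis %in% c("extra_strong1", "exon2_only")) cds_chars[4] <- "G"
  # strong +4 for the exon-2 ATG in weak1_strong2: the exon-2 TIS is the
  # next in-frame ATG; plant one at the start of exon 2's CDS
  if (tis %in% c("weak1_strong2", "exon2_only")) {
    off <- if (tis == "weak1_strong2") exon1_cds_len else 0L
    cds_chars[(off + 1):(off + 3)] <- c("A", "T", "G")
    if (off >= 3) cds_chars[off - 2] <- "A"      # -3 purine (in coding seq)
    cds_chars[off + 4] <- "A"                    # +4 purine
  }
  cds <- paste0(cds_chars, collapse = "")
  # keep reading frame stop-free after edits
  cods <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  internal <- cods[-length(cods)]
  bad <- which(internal %in% STOP_CODONS)
  for (b in bad) {
    cods[b] <- "CTG"
  }
  cds <- paste0(cods, collapse = "")

  # 3' UTR with planted hexamers
  utr3 <- strsplit(rnt_no_atg(utr3_length), "")[[1]]
  for (i in seq_along(polya_offsets)) {
    o <- polya_offsets[i]
    if (o + 5 > utr3_length) stop("polyA offset beyond UTR length")
    utr3[o:(o + 5)] <- strsplit(polya_motifs[i], "")[[1]]
  }
  # remove accidental hexamer hits outside planted spans
  utr3 <- paste0(utr3, collapse = "")
  planted <- unlist(lapply(polya_offsets, function(o) o:(o + 5)))
  repeat {
    hits <- scan_polya(utr3)
    stray <- hits$start[!hits$start %in% polya_offsets]
    if (!length(stray)) break
    p <- stray[1]
    substr(utr3, p + 2, p + 2) <- "G"  # break the motif
  }

  mrna_cds <- paste0(utr5, cds, utr3)

  # genomic assembly: exons separated by introns; the exon7-exon10
  # intron carries the planted 39-bp copies
  exon_seqs <- character(13)
  # cut mRNA into exons: exon 1 = utr5 + exon1_cds_len
  cuts <- c(nchar(utr5) + exon1_cds_len,
            cumsum(exon_cds_len[-1]) + nchar(utr5) + exon1_cds_len)
  # exon 13 takes the 3'UTR too
  bounds <- c(0, cuts[-length(cuts)], nchar(mrna_cds))
  for (i in 1:13)
    exon_seqs[i] <- substr(mrna_cds, bounds[i] + 1, bounds[i + 1])
  exon7 <- exon_seqs[7]
  stopifnot(nchar(exon7) == 39)

  mutate_copy <- function(s, ident) {
    ch <- strsplit(s, "")[[1]]
    n_mut <- round((1 - ident) * length(ch))
    if (n_mut > 0) {
      at <- sample(seq_along(ch), n_mut)
      ch[at] <- vapply(ch[at], function(b) sample(setdiff(nt, b), 1L), "")
    }
    paste0(ch, collapse = "")
  }

  intron <- function(n) rnt_no_atg(n)
  introns <- vapply(c(300, 200, 250, 180, 220, 240, 0, 150, 160, 170, 190, 210),
                    intron, "")
  # build intron between exon 7 and 8 region with planted copies spaced out
  dup_truth <- NULL
  if (n_exon7_copies > 0) {
    # copies live between exon 7 and exon 10; distribute them in the
    # introns 7-8, 8-9, 9-10 region modelled as one search space
    pieces <- character(0)
    offs <- integer(0)
    cursor <- 0L
    for (i in seq_len(n_exon7_copies)) {
      gap <- intron(60)
      copy <- paste0("AG", mutate_copy(exon7, copy_identity), "GT")
      pieces <- c(pieces, gap, copy)
      offs <- c(offs, cursor + 60L + 2L + 1L)  # start of copy seq
      cursor <- cursor + 60L + nchar(copy)
    }
    dup_region <- paste0(paste0(pieces, collapse = ""), intron(60))
    dup_truth <- data.frame(start = offs, end = offs + 38L,
                            identity = copy_identity)
  } else {
    dup_region <- intron(200)
  }
  introns[7] <- dup_region

  genomic <- exon_seqs[1]
  starts <- integer(13); ends <- integer(13)
  starts[1] <- 1L; ends[1] <- nchar(exon_seqs[1])
  for (i in 2:13) {
    genomic <- paste0(genomic, introns[i - 1], exon_seqs[i])
    starts[i] <- nchar(genomic) - nchar(exon_seqs[i]) + 1L
    ends[i] <- nchar(genomic)
  }
  exons <- data.frame(exon_id = paste0("exon", 1:13),
                      start = starts, end = ends)
  # CDS genomic span
  utr5_len <- nchar(utr5)
  # position of CDS start within exon 1 coordinates (or exon 2)
  if (exon1_cds_len > 0 || tis != "exon2_only") {
    cds_start_g <- starts[1] + utr5_len
  } else {
    # utr5 fills exon 1 entirely plus start of exon 2
    rem <- utr5_len - nchar(exon_seqs[1])
    cds_start_g <- starts[2] + rem
  }
  cds_len <- nchar(cds)
  # map spliced CDS end to genomic: walk exons
  gpos <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
  sp_cds_start <- match(cds_start_g, gpos)
  cds_end_g <- gpos[sp_cds_start + cds_len - 1L]

  gm <- gene_model("fixture", genomic, exons, cds_start_g, cds_end_g)
  polya_truth <- data.frame(ps = paste0("PS", order(order(polya_offsets))),
                            motif = polya_motifs,
                            start = polya_offsets, end = polya_offsets + 5L)
  polya_truth <- polya_truth[order(polya_truth$start), ]
  list(gene = gm,
       truth = list(tis = tis_truth, layout = tis,
                    polya = polya_truth, duplications = dup_truth,
                    dup_region = dup_region, exon7 = exon7, seed = seed))
}
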