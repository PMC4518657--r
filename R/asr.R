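# Marginal ancestral sequence reconstruction: exact per-node posteriors
# from an up-down pass over the tree, mixed over site classes with
# empirical-Bayes weights; alignment gaps are reconstructed separately by
# Fitch presence/absence parsimony.

#' Marginal ancestral state reconstruction
#'
#' Computes, for every internal node and codon column, the exact
#' marginal posterior over the 61 sense codons under the fitted model
#' (classes weighted by their per-site empirical-Bayes posteriors), and
#' the MAP codon. The gap/missing pattern is reconstructed as a binary
#' presence/absence character by Fitch parsimony with ties resolved to
#' present; reconstructed codons at absent positions are reported but
#' flagged.
#'
#' @param fit A `codon_fit` from [fit_codon_model()] on a rooted tree.
#' @param keep_posteriors Return the full posterior array (default
#'   `TRUE`; set `FALSE` to save memory on large problems).
#' @return List with `map_codon` and `map_aa` (internal-node x site
#'   character matrices), `map_prob` (posterior of the MAP codon),
#'   `present` (logical, Fitch gap reconstruction) and optionally
#'   `posterior` (node x 61 x site array).
#' @export
marginal_ancestral_states <- function(fit, keep_posteriors = TRUE) {
  stopifnot(inherits(fit, "codon_fit"))
  tree <- fit$tree
  if (!ape::is.rooted(tree))
    stop("ancestral reconstruction needs a rooted tree (designate an outgroup)")
  aln <- fit$aln
  states <- codon_state_matrix(aln, taxa = tree$tip.label)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  el <- tr$edge.length * fit$scale
  n_node <- max(tr$edge)
  n_site <- ncol(states)
  ns <- length(fit$pi)
  internal <- (ntip + 1L):n_node

  # class structure and per-site class weights
  if (fit$kind == "branch") {
    # treat as single-class with per-edge generators
    class_w <- matrix(1, 1, n_site)
    omegas <- NA
  } else {
    props <- fit$model$props
    omegas <- fit$model$omegas
    class_w <- class_posterior(fit$class_loglik, props)
    keep <- colSums(class_w) > 0
  }
  n_class <- nrow(class_w)

  post_total <- array(0, dim = c(length(internal), ns, n_site))

  edge_cls <- if (fit$kind == "branch")
    reorder_edge_attribute(tree, tr, as.integer(fit$branch_spec)) else NULL

  for (k in seq_len(n_class)) {
    wk <- class_w[k, ]
    if (all(wk < 1e-12)) next
    # per-edge P matrices for this class
    P <- vector("list", nrow(tr$edge))
    if (fit$kind == "branch") {
      decs <- lapply(fit$branch_omegas, function(w) {
        Q <- build_rate_matrix(fit$kappa, w, fit$pi)
        list(Q = Q, dec = decompose_generator(Q, fit$pi))
      })
      for (e in seq_along(P)) {
        d <- decs[[edge_cls[e] + 1L]]
        P[[e]] <- transition_matrix(d$dec, d$Q, el[e])
      }
    } else {
      Q <- build_rate_matrix(fit$kappa, omegas[k], fit$pi)
      dec <- decompose_generator(Q, fit$pi)
      for (e in seq_along(P)) P[[e]] <- transition_matrix(dec, Q, el[e])
    }

    # downward pass: partials per node, scaled per site
    down <- vector("list", n_node)
    for (i in seq_len(ntip)) {
      m <- matrix(0, ns, n_site)
      st <- states[i, ]
      ok <- !is.na(st)
      m[cbind(st[ok], which(ok))] <- 1
      m[, !ok] <- 1
      down[[i]] <- m
    }
    trans <- vector("list", nrow(tr$edge))  # P_e %*% down_child per edge
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      trans[[e]] <- P[[e]] %*% down[[ch]]
      if (is.null(down[[par]])) down[[par]] <- trans[[e]]
      else down[[par]] <- down[[par]] * trans[[e]]
      mx <- apply(down[[par]], 2L, max)
      mx[mx == 0] <- 1
      down[[par]] <- sweep(down[[par]], 2L, mx, "/")
    }

    # upward pass (preorder = reverse postorder edges)
    root <- tr$edge[nrow(tr$edge), 1]
    up <- vector("list", n_node)
    up[[root]] <- matrix(fit$pi, ns, n_site)
    child_edges <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      if (ch <= ntip) next
      sib <- setdiff(child_edges[[as.character(par)]], e)
      prod_sib <- up[[par]]
      for (se in sib) prod_sib <- prod_sib * trans[[se]]
      up[[ch]] <- crossprod(P[[e]], prod_sib)
      mx <- apply(up[[ch]], 2L, max)
      mx[mx == 0] <- 1
      up[[ch]] <- sweep(up[[ch]], 2L, mx, "/")
    }

    for (j in seq_along(internal)) {
      v <- internal[j]
      raw <- up[[v]] * down[[v]]
      tot <- colSums(raw)
      tot[tot == 0] <- NA
      post_total[j, , ] <- post_total[j, , ] +
        sweep(raw, 2L, tot, "/") * rep(wk, each = ns)
    }
  }

  map_idx <- apply(post_total, c(1, 3), which.max)
  map_prob <- apply(post_total, c(1, 3), max)
  codons <- sense_codons()
  map_codon <- matrix(codons[map_idx], nrow = length(internal),
                      dimnames = list(paste0("node_", internal), NULL))
  map_aa <- matrix(translate_codons(codons[map_idx]),
                   nrow = length(internal),
                   dimnames = list(paste0("node_", internal), NULL))
  present <- fitch_gap_reconstruction(tree, !is.na(states))
  out <- list(map_codon = map_codon, map_aa = map_aa,
              map_prob = matrix(map_prob, nrow = length(internal),
                                dimnames = list(paste0("node_", internal), NULL)),
              present = present, nodes = internal)
  if (keep_posteriors) {
    dimnames(post_total) <- list(paste0("node_", internal), codons, NULL)
    out$posterior <- post_total
  }
  out
}

# Fitch presence/absence over every column; ties at a node -> present.
# tip_present: ntip x nsite logical.
fitch_gap_reconstruction <- function(tree, tip_present) {
  anc <- fitch_parsimony(tree, ifelse(tip_present, 1L, 0L))
  st <- anc$states
  st[st == "ambiguous"] <- "1"
  out <- st == "1"
  rownames(out) <- rownames(anc$states)
  out
}
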