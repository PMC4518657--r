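# Site-class model specifications: M0 (one ratio), M7 (beta-distributed
# omega on (0,1)) and M8 (beta plus a selection class with omega >= 1).
# The beta is discretized into k equal-probability categories represented
# by their medians, the convention of mainstream codon-model software.

#' Site-class model specification
#'
#' @param kind `"M0"`, `"M7"` or `"M8"`.
#' @param omega M0 only: the single dN/dS ratio.
#' @param p,q Beta shape parameters (M7/M8).
#' @param p0 M8 only: proportion of sites in the beta component.
#' @param omega_s M8 only: dN/dS of the selection class (>= 1).
#' @param k Number of discrete beta categories (default 10).
#' @return Object of class `site_class_model` with fields `omegas`
#'   (class dN/dS values) and `props` (class proportions, summing to 1).
#' @export
site_class_model <- function(kind = c("M0", "M7", "M8"), omega = 0.4,
                             p = 1, q = 1, p0 = 0.9, omega_s = 2, k = 10) {
  kind <- match.arg(kind)
  out <- switch(kind,
    M0 = {
      if (omega < 0) stop("omega must be >= 0")
      list(omegas = omega, props = 1)
    },
    M7 = {
      list(omegas = beta_class_omegas(p, q, k), props = rep(1 / k, k))
    },
    M8 = {
      if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
      if (omega_s < 1) stop("M8 selection-class omega must be >= 1")
      list(omegas = c(beta_class_omegas(p, q, k), omega_s),
           props = c(rep(p0 / k, k), 1 - p0))
    })
  structure(c(list(kind = kind, k = k,
                   params = switch(kind,
                     M0 = list(omega = omega),
                     M7 = list(p = p, q = q),
                     M8 = list(p = p, q = q, p0 = p0, omega_s = omega_s))),
              out),
            class = "site_class_model")
}

# medians of k equal-probability Beta(p, q) categories; qbeta's accuracy
# warnings at the extreme shapes the optimizer probes are harmless here
# (category medians only need a few digits), so they are muffled and the
# result clamped inside (0, 1)
beta_class_omegas <- function(p, q, k) {
  if (p <= 0 || q <= 0) stop("beta shapes must be > 0")
  x <- suppressWarnings(stats::qbeta((2 * seq_len(k) - 1) / (2 * k), p, q))
  pmin(pmax(x, 1e-9), 1 - 1e-9)
}

#' @export
print.site_class_model <- function(x, ...) {
  cat("site_class_model", x$kind, "-", length(x$omegas), "omega classes\n")
  cat("params:", paste(names(x$params), signif(unlist(x$params), 4),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# --- likelihood layer ------------------------------------------------------

# Per-class per-site log-likelihood matrix (n_class x n_site).
# branch_cls: NULL for uniform branches, else integer class per edge with
# omegas_by_class overriding the site-class mixture (single "class").
class_site_loglik <- function(states, tree, omegas, kappa, pi,
                              scale = 1, branch_omegas = NULL,
                              branch_cls = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  el <- tr$edge.length * scale
  n_node <- max(tr$edge)
  if (is.null(branch_cls)) {
    ll <- matrix(NA_real_, length(omegas), ncol(states))
    for (kk in seq_along(omegas)) {
      Q <- build_rate_matrix(kappa, omegas[kk], pi)
      dec <- decompose_generator(Q, pi)
      if (isTRUE(dec$fallback)) {
        P <- transition_cube(dec, Q, el)
        ll[kk, ] <- cpp_prune_loglik(states, tr$edge, P, pi, n_node)
      } else {
        ll[kk, ] <- cpp_prune_loglik_eig(states, tr$edge, dec$U, dec$Uinv,
                                         dec$values, el, pi, n_node)
      }
    }
    ll
  } else {
    # multi-ratio branch model: one generator per ratio class, edges mixed
    edge_cls <- reorder_edge_attribute(tree, tr, branch_cls)
    n <- length(pi)
    P <- array(0, dim = c(n, n, nrow(tr$edge)))
    for (r in seq_along(branch_omegas)) {
      idx <- which(edge_cls == (r - 1L))
      if (!length(idx)) next
      Q <- build_rate_matrix(kappa, branch_omegas[r], pi)
      dec <- decompose_generator(Q, pi)
      for (e in idx) P[, , e] <- transition_matrix(dec, Q, el[e])
    }
    matrix(cpp_prune_loglik(states, tr$edge, P, pi, n_node), nrow = 1)
  }
}

# map an edge-ordered attribute from the original tree to postorder order
reorder_edge_attribute <- function(tree, tr_post, x) {
  key_orig <- paste(tree$edge[, 1], tree$edge[, 2])
  key_post <- paste(tr_post$edge[, 1], tr_post$edge[, 2])
  x[match(key_post, key_orig)]
}

#' Per-site and total log-likelihood under a site-class model
#'
#' Computes the Felsenstein pruning likelihood for every codon column as
#' a proportion-weighted mixture over the model's dN/dS classes. Missing
#' states contribute partial-likelihood vectors of ones, so a fully
#' missing leaf is uninformative.
#'
#' @param aln A [codon_alignment()].
#' @param tree An [ape::phylo] tree whose tips match `aln$taxa`; branch
#'   lengths in expected substitutions per codon.
#' @param model A [site_class_model()].
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default: F3x4 from `aln`).
#' @param scale Multiplier applied to all branch lengths.
#' @param branch_spec Optional [branch_classes()] with `branch_omegas`
#'   giving one dN/dS per ratio class (overrides `model`'s mixture).
#' @param branch_omegas Per-class dN/dS values when `branch_spec` given.
#' @return List with `site_loglik` (per-column log-likelihood), `loglik`
#'   (their sum) and `class_loglik` (n_class x n_site matrix).
#' @export
site_log_likelihood <- function(aln, tree, model, kappa = 2, pi = NULL,
                                scale = 1, branch_spec = NULL,
                                branch_omegas = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(pi)) pi <- codon_frequencies(aln)
  if (length(aln$taxa) == 1L) {
    # closed form: a lone sequence contributes only the root prior
    st <- codon_state_matrix(aln)[1, ]
    site_ll <- ifelse(is.na(st), 0, log(pi[st]))
    return(list(site_loglik = unname(site_ll), loglik = sum(site_ll),
                class_loglik = matrix(site_ll, nrow = 1)))
  }
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, aln$taxa))
    stop("tree tip labels and alignment taxa differ")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  states <- codon_state_matrix(aln, taxa = tree$tip.label)
  if (is.null(branch_spec)) {
    ll <- class_site_loglik(states, tree, model$omegas, kappa, pi, scale)
    site_ll <- mixture_loglik(ll, model$props)
  } else {
    if (is.null(branch_omegas))
      stop("branch_omegas required with branch_spec")
    ll <- class_site_loglik(states, tree, NULL, kappa, pi, scale,
                            branch_omegas = branch_omegas,
                            branch_cls = as.integer(branch_spec))
    site_ll <- ll[1, ]
  }
  if (any(!is.finite(site_ll)))
    stop("non-finite site log-likelihood at column(s) ",
         paste(utils::head(which(!is.finite(site_ll)), 5), collapse = ", "))
  list(site_loglik = site_ll, loglik = sum(site_ll), class_loglik = ll)
}

# log(sum_k w_k exp(ll_k)) per column, stable
mixture_loglik <- function(ll, props) {
  keep <- props > 0
  ll <- ll[keep, , drop = FALSE]
  lw <- log(props[keep])
  m <- apply(ll, 2L, max)
  m + log(colSums(exp(ll - rep(m, each = nrow(ll))) * exp(lw)))
}
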