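# Goldman-Yang codon substitution machinery: equilibrium frequency
# estimators, the 61x61 generator, and transition matrices via
# eigendecomposition of the reversible model.

#' Codon equilibrium frequencies
#'
#' Estimates the stationary codon distribution from an alignment.
#' `"F3x4"` (default) multiplies the empirical nucleotide frequencies at
#' the three codon positions and renormalizes over sense codons; `"F61"`
#' uses empirical codon counts. Zero frequencies are floored at `floor`
#' and the vector renormalized, so every sense codon remains reachable.
#'
#' @param aln A [codon_alignment()].
#' @param method `"F3x4"` or `"F61"`.
#' @param floor Minimum frequency before renormalization.
#' @return Numeric vector over [sense_codons()], summing to 1.
#' @export
codon_frequencies <- function(aln, method = c("F3x4", "F61"), floor = 1e-8) {
  method <- match.arg(method)
  cod <- aln$codons[!is.na(aln$codons)]
  sc <- sense_codons()
  if (method == "F61") {
    counts <- table(factor(cod, levels = sc))
    pi <- as.numeric(counts) / sum(counts)
  } else {
    mat <- do.call(rbind, strsplit(cod, ""))
    nt <- c("A", "C", "G", "T")
    fpos <- vapply(1:3, function(p) {
      tab <- table(factor(mat[, p], levels = nt))
      as.numeric(tab) / sum(tab)
    }, numeric(4))  # 4 x 3
    scm <- do.call(rbind, strsplit(sc, ""))
    pi <- fpos[match(scm[, 1], nt), 1] *
          fpos[match(scm[, 2], nt), 2] *
          fpos[match(scm[, 3], nt), 3]
    pi <- pi / sum(pi)
  }
  floored <- pi < floor
  if (any(floored)) {
    pi[floored] <- floor
    pi <- pi / sum(pi)
  }
  names(pi) <- sc
  attr(pi, "floored") <- any(floored)
  attr(pi, "method") <- method
  pi
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61x61 generator Q with entries for single-nucleotide
#' changes: `q_ij = pi_j * {1, kappa, omega, omega*kappa}` for
#' synonymous transversions/transitions and nonsynonymous
#' transversions/transitions respectively; multi-nucleotide changes and
#' changes through stop codons are 0. The matrix is scaled so the mean
#' rate at stationarity is 1, i.e. branch lengths are expected
#' substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi Equilibrium frequencies over [sense_codons()].
#' @param scale Rescale to unit mean rate (default `TRUE`).
#' @return 61x61 generator matrix (rows sum to 0).
#' @export
build_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  pt <- codon_pair_table()
  n <- length(pi)
  fac <- matrix(0, n, n)
  fac[pt$single & pt$transition & pt$synonymous] <- kappa
  fac[pt$single & !pt$transition & pt$synonymous] <- 1
  fac[pt$single & pt$transition & !pt$synonymous] <- kappa * omega
  fac[pt$single & !pt$transition & !pt$synonymous] <- omega
  Q <- fac * rep(pi, each = n)  # q_ij = fac_ij * pi_j
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  dimnames(Q) <- list(sense_codons(), sense_codons())
  Q
}

# Spectral decomposition of a reversible generator via symmetrization:
# S = D^{1/2} Q D^{-1/2} is symmetric for reversible Q, so
# P(t) = U exp(L t) Uinv with U = D^{-1/2} V, Uinv = V' D^{1/2}.
decompose_generator <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  U <- eig$vectors / sp
  Uinv <- t(eig$vectors) * rep(sp, each = length(sp))
  dec <- list(U = U, Uinv = Uinv, values = eig$values)
  # sanity: reconstruction must reproduce Q; fall back to series expm if
  # flooring made the symmetrization ill-conditioned
  err <- max(abs(U %*% (eig$values * Uinv) - Q))
  if (!is.finite(err) || err > 1e-6 * max(1, max(abs(Q)))) {
    dec$fallback <- TRUE
  }
  dec
}

# P(t) for one decomposed generator; clamps tiny negatives from roundoff
transition_matrix <- function(dec, Q, t) {
  if (isTRUE(dec$fallback)) {
    P <- as.matrix(Matrix::expm(Q * t))
  } else {
    P <- dec$U %*% (exp(dec$values * t) * dec$Uinv)
  }
  P[P < 0] <- 0
  P
}

# 61 x 61 x nedge cube of per-edge P matrices for one generator
transition_cube <- function(dec, Q, edge_lengths) {
  n <- nrow(Q)
  P <- array(0, dim = c(n, n, length(edge_lengths)))
  for (e in seq_along(edge_lengths))
    P[, , e] <- transition_matrix(dec, Q, edge_lengths[e])
  P
}
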