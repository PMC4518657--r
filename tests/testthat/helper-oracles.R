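# Independent oracles and small fixture builders shared across tests.
# The oracles never reuse the package's likelihood path: the rate matrix
# is rebuilt from the codon table from first principles and exponentiated
# with Matrix::expm.

oracle_codons <- function() {
  nt <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(nt, nt, nt)[, 3:1], 1, paste0, collapse = ""))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

oracle_gy_matrix <- function(kappa, omega, pi) {
  cod <- oracle_codons()
  gc <- Biostrings::GENETIC_CODE
  n <- length(cod)
  Q <- matrix(0, n, n, dimnames = list(cod, cod))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    ci <- strsplit(cod[i], "")[[1]]; cj <- strsplit(cod[j], "")[[1]]
    diff <- which(ci != cj)
    if (length(diff) != 1) next
    ts <- paste0(sort(c(ci[diff], cj[diff])), collapse = "") %in% c("AG", "CT")
    syn <- gc[[cod[i]]] == gc[[cod[j]]]
    r <- pi[j]
    if (ts) r <- r * kappa
    if (!syn) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# brute-force codon-site likelihood on the 3-taxon tree ((A:ta,B:tb):ti,C:tc)
# by enumerating both internal node states
oracle_loglik_3taxa <- function(states_abc, kappa, omega, pi,
                                ta, tb, ti, tc) {
  Q <- oracle_gy_matrix(kappa, omega, pi)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  PA <- P(ta); PB <- P(tb); PI <- P(ti); PC <- P(tc)
  a <- states_abc[1]; b <- states_abc[2]; cc <- states_abc[3]
  tot <- 0
  for (r in seq_along(pi)) for (x in seq_along(pi)) {
    la <- if (is.na(a)) 1 else PA[x, a]
    lb <- if (is.na(b)) 1 else PB[x, b]
    lc <- if (is.na(cc)) 1 else PC[r, cc]
    tot <- tot + pi[r] * lc * PI[r, x] * la * lb
  }
  unname(log(tot))
}

# brute-force marginal root/internal posteriors for the same 3-taxon tree
oracle_posterior_3taxa <- function(states_abc, kappa, omega, pi,
                                   ta, tb, ti, tc) {
  Q <- oracle_gy_matrix(kappa, omega, pi)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  PA <- P(ta); PB <- P(tb); PI <- P(ti); PC <- P(tc)
  a <- states_abc[1]; b <- states_abc[2]; cc <- states_abc[3]
  n <- length(pi)
  joint <- matrix(0, n, n)  # root r x inner x
  for (r in 1:n) for (x in 1:n) {
    la <- if (is.na(a)) 1 else PA[x, a]
    lb <- if (is.na(b)) 1 else PB[x, b]
    lc <- if (is.na(cc)) 1 else PC[r, cc]
    joint[r, x] <- pi[r] * lc * PI[r, x] * la * lb
  }
  list(root = rowSums(joint) / sum(joint),
       inner = colSums(joint) / sum(joint))
}

# minimum-change count and root-state set for a binary character by
# exhaustive assignment of internal-node states
oracle_fitch_root <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  internal <- (ntip + 1):n_node
  best <- Inf; root_states <- integer(0)
  combos <- expand.grid(rep(list(0:1), length(internal)))
  for (i in seq_len(nrow(combos))) {
    assign_full <- c(tip_states, as.integer(combos[i, ]))
    changes <- sum(assign_full[tree$edge[, 1]] != assign_full[tree$edge[, 2]])
    rs <- assign_full[ntip + 1]
    if (changes < best) { best <- changes; root_states <- rs }
    else if (changes == best) root_states <- union(root_states, rs)
  }
  list(score = best, root = sort(root_states))
}

uniform_pi <- function() {
  stats::setNames(rep(1 / 61, 61), sense_codons())
}

# quick random codon alignment (no evolution; for parser/format tests)
random_codon_matrix <- function(ntaxa, ncodons, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(sense_codons(), ntaxa * ncodons, replace = TRUE),
              nrow = ntaxa)
  rownames(m) <- paste0("t", seq_len(ntaxa))
  m
}

# minimal hand-built codon_fit for posterior arithmetic tests
toy_fit <- function(class_loglik, omegas, props) {
  structure(list(kind = "M8", lnL = sum(class_loglik),
                 model = list(omegas = omegas, props = props,
                              params = list()),
                 class_loglik = class_loglik),
            class = "codon_fit")
}
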