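// Felsenstein pruning over the 61-state codon alphabet, with per-site
// rescaling to avoid underflow on large trees. Tips enter as integer
// states (1..61, NA = missing); transition matrices are supplied per
// edge as a cube computed in R from the model's eigendecomposition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the per-edge transition cube from the generator's spectral
// decomposition (P_e = U diag(exp(lambda t_e)) Uinv) and run the pruning
// in one call; avoids R-level allocation in the optimizer's hot loop.
// [[Rcpp::export]]
arma::vec cpp_prune_loglik_eig(const IntegerMatrix tip_states,
                               const IntegerMatrix edge,
                               const arma::mat& U,
                               const arma::mat& Uinv,
                               const arma::vec& eigval,
                               const arma::vec& edge_len,
                               const arma::vec& pi,
                               const int n_node);

// tip_states: ntip x nsite integer matrix, 1-based codon state, NA missing
// edge: nedge x 2 (parent, child), ape node numbering, postorder
// P: 61 x 61 x nedge transition matrices, P(i,j) = Pr(j at child | i at parent)
// pi: root frequencies (length 61)
// returns per-site log-likelihood (length nsite)
// [[Rcpp::export]]
arma::vec cpp_prune_loglik(const IntegerMatrix tip_states,
                           const IntegerMatrix edge,
                           const arma::cube& P,
                           const arma::vec& pi,
                           const int n_node) {
  const int ntip = tip_states.nrow();
  const int nsite = tip_states.ncol();
  const int nedge = edge.nrow();
  const int nstate = P.n_rows;

  // partial likelihoods for internal nodes only, lazily initialised to 1
  std::vector<arma::mat> part(n_node + 1);
  std::vector<bool> init(n_node + 1, false);
  arma::rowvec scaler(nsite, arma::fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0);
    const int child = edge(e, 1);
    arma::mat contrib(nstate, nsite);
    if (child <= ntip) {
      const arma::mat& Pe = P.slice(e);
      for (int s = 0; s < nsite; ++s) {
        const int st = tip_states(child - 1, s);
        if (st == NA_INTEGER) {
          contrib.col(s).ones();
        } else {
          contrib.col(s) = Pe.col(st - 1);
        }
      }
    } else {
      if (!init[child])
        stop("postorder violation: internal child visited before its subtree");
      contrib = P.slice(e) * part[child];
      part[child].reset();  // free
    }
    if (!init[parent]) {
      part[parent] = contrib;
      init[parent] = true;
    } else {
      part[parent] %= contrib;
    }
    // rescale parent partials per site
    arma::rowvec m = arma::max(part[parent], 0);
    for (int s = 0; s < nsite; ++s) {
      double ms = m(s);
      if (ms > 0 && (ms < 1e-80 || ms > 1e80)) {
        part[parent].col(s) /= ms;
        scaler(s) += std::log(ms);
      }
    }
  }

  const int root = edge(nedge - 1, 0);
  if (!init[root]) stop("root partials not computed");
  arma::vec out(nsite);
  for (int s = 0; s < nsite; ++s) {
    double L = arma::dot(pi, part[root].col(s));
    out(s) = (L > 0) ? std::log(L) + scaler(s) : -arma::datum::inf;
  }
  return out;
}

arma::vec cpp_prune_loglik_eig(const IntegerMatrix tip_states,
                               const IntegerMatrix edge,
                               const arma::mat& U,
                               const arma::mat& Uinv,
                               const arma::vec& eigval,
                               const arma::vec& edge_len,
                               const arma::vec& pi,
                               const int n_node) {
  const int nedge = edge.nrow();
  const int nstate = U.n_rows;
  arma::cube P(nstate, nstate, nedge);
  for (int e = 0; e < nedge; ++e) {
    arma::mat M = Uinv;
    M.each_col() %= arma::exp(eigval * edge_len(e));
    P.slice(e) = U * M;
    P.slice(e).transform([](double v) { return v < 0 ? 0.0 : v; });
  }
  return cpp_prune_loglik(tip_states, edge, P, pi, n_node);
}
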