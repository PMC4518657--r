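test_that("rate matrix has GY94 structure", {
  pi <- uniform_pi()
  Q0 <- build_rate_matrix(2, 0, pi, scale = FALSE)
  aa <- translate_codons(sense_codons())
  nonsyn <- outer(aa, aa, "!=")
  expect_true(all(Q0[nonsyn] == 0))
  expect_equal(max(abs(rowSums(Q0))), 0, tolerance = 1e-12)

  # kappa=1, omega=1, uniform pi: all single-nt neighbour rates equal
  Q1 <- build_rate_matrix(1, 1, pi, scale = FALSE)
  off <- Q1[upper.tri(Q1) | lower.tri(Q1)]
  expect_equal(sort(unique(round(off[off > 0], 12))), 1 / 61)

  # syn transition vs nonsyn transversion: q(TTT->TTC)/q(TTT->TTA) = kappa/omega
  Q2 <- build_rate_matrix(2, 0.5, pi)
  expect_equal(Q2["TTT", "TTC"] / Q2["TTT", "TTA"], 4)
  # multi-nucleotide changes are forbidden
  expect_equal(Q2["TTT", "AAT"], 0)
  expect_equal(Q2["TTT", "CCC"], 0)
  # mean rate scaled to 1
  expect_equal(-sum(pi * diag(Q2)), 1, tolerance = 1e-12)

  expect_error(build_rate_matrix(-1, 0.5, pi), "kappa")
  expect_error(build_rate_matrix(2, 0.5, pi * 2), "sum")
})

test_that("transition matrices are stochastic and stationary", {
  set.seed(7)
  aln <- codon_alignment(random_codon_matrix(8, 60, seed = 8))
  for (pi in list(uniform_pi(), codon_frequencies(aln, "F3x4"),
                  codon_frequencies(aln, "F61"))) {
    Q <- build_rate_matrix(2.3, 0.7, pi)
    dec <- omegascan:::decompose_generator(Q, pi)
    for (t in c(0.01, 0.3, 2, 10)) {
      P <- omegascan:::transition_matrix(dec, Q, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
      expect_lt(max(abs(pi %*% P - pi)), 1e-10)
      expect_true(all(P >= 0))
    }
  }
})

test_that("F3x4 and F61 frequencies are valid and floored", {
  aln <- codon_alignment(random_codon_matrix(4, 40, seed = 2))
  for (m in c("F3x4", "F61")) {
    pi <- codon_frequencies(aln, m)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi > 0))
  }
  # F61 on a tiny alignment floors unseen codons
  small <- codon_alignment(rbind(a = c("ATG", "ATG"), b = c("ATG", "ATG")))
  pi61 <- codon_frequencies(small, "F61")
  expect_true(attr(pi61, "floored"))
  expect_true(all(pi61 > 0))
})

test_that("pruning likelihood matches brute-force enumeration", {
  pi <- uniform_pi()
  tr <- ape::read.tree(text = "((A:0.2,B:0.35):0.15,C:0.4);")
  m <- site_class_model("M0", omega = 0.5)
  sim <- simulate_codon_alignment(tr, m, n_codons = 4, seed = 11)
  aln <- sim$alignment
  st <- codon_alignment(aln$codons[c("A", "B", "C"), ])
  states <- matrix(match(st$codons, sense_codons()), nrow = 3)
  ll <- site_log_likelihood(aln, tr, m, kappa = 2, pi = pi)
  for (s in 1:4) {
    exp_ll <- oracle_loglik_3taxa(states[, s], 2, 0.5, pi,
                                  0.2, 0.35, 0.15, 0.4)
    expect_equal(ll$site_loglik[s], exp_ll, tolerance = 1e-8)
  }
  # with a missing state
  aln2 <- aln
  aln2$codons["B", 2] <- NA
  states[2, 2] <- NA
  ll2 <- site_log_likelihood(codon_alignment(aln2$codons), tr, m,
                             kappa = 2, pi = pi)
  expect_equal(ll2$site_loglik[2],
               oracle_loglik_3taxa(states[, 2], 2, 0.5, pi,
                                   0.2, 0.35, 0.15, 0.4),
               tolerance = 1e-8)
})

test_that("site independence: duplicating columns doubles total lnL", {
  tr <- simulate_tree(6, seed = 3)
  m <- site_class_model("M7", p = 2, q = 3, k = 4)
  sim <- simulate_codon_alignment(tr, m, 30, seed = 5)
  pi <- codon_frequencies(sim$alignment)
  ll1 <- site_log_likelihood(sim$alignment, tr, m, pi = pi)
  dup <- codon_alignment(cbind(sim$alignment$codons, sim$alignment$codons))
  ll2 <- site_log_likelihood(dup, tr, m, pi = pi)
  expect_equal(ll2$loglik, 2 * ll1$loglik, tolerance = 1e-10)
})

test_that("single sequence has closed-form likelihood ln pi(codon)", {
  pi <- uniform_pi()
  aln <- codon_alignment(matrix(c("ATG", "GCT", NA), nrow = 1,
                                dimnames = list("a", NULL)))
  ll <- site_log_likelihood(aln, NULL, site_class_model("M0"), pi = pi)
  expect_equal(ll$site_loglik, c(log(pi["ATG"]), log(pi["GCT"]), 0),
               ignore_attr = TRUE)
})

test_that("an all-missing leaf does not constrain the likelihood", {
  star <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.3,D:0.25);")
  m <- site_class_model("M0", omega = 0.4)
  sim <- simulate_codon_alignment(ape::read.tree(text = "(A:0.1,B:0.2,C:0.3);"),
                                  m, 20, seed = 9)
  pi <- uniform_pi()
  ll3 <- site_log_likelihood(sim$alignment,
                             ape::read.tree(text = "(A:0.1,B:0.2,C:0.3);"),
                             m, pi = pi)
  with_missing <- rbind(sim$alignment$codons,
                        D = rep(NA_character_, 20))
  ll4 <- site_log_likelihood(codon_alignment(with_missing), star, m, pi = pi)
  expect_equal(ll4$loglik, ll3$loglik, tolerance = 1e-9)
})

test_that("likelihood is invariant to re-rooting for reversible models", {
  tr <- simulate_tree(8, seed = 13)
  m <- site_class_model("M0", omega = 0.6)
  sim <- simulate_codon_alignment(tr, m, 40, seed = 14)
  pi <- codon_frequencies(sim$alignment)
  ll <- site_log_likelihood(sim$alignment, tr, m, pi = pi)$loglik
  for (node in c(2L, 5L)) {
    rerooted <- ape::root(tr, outgroup = tr$tip.label[node],
                          resolve.root = TRUE)
    llr <- site_log_likelihood(sim$alignment, rerooted, m, pi = pi)$loglik
    expect_equal(llr, ll, tolerance = 1e-8)
  }
})

test_that("M8 with p1 = 0 collapses to M7", {
  tr <- simulate_tree(6, seed = 21)
  sim <- simulate_codon_alignment(tr, site_class_model("M7", p = 1.5, q = 4,
                                                       k = 6), 40, seed = 22)
  pi <- codon_frequencies(sim$alignment)
  m7 <- site_class_model("M7", p = 1.5, q = 4, k = 6)
  m8 <- site_class_model("M8", p = 1.5, q = 4, p0 = 1, omega_s = 2, k = 6)
  l7 <- site_log_likelihood(sim$alignment, tr, m7, pi = pi)$loglik
  l8 <- site_log_likelihood(sim$alignment, tr, m8, pi = pi)$loglik
  expect_lt(abs(l7 - l8), 1e-6)
})

test_that("lrt arithmetic and chi-square tails behave", {
  f1 <- structure(list(kind = "M7", lnL = -1000, n_free_params = 4),
                  class = "codon_fit")
  f2 <- structure(list(kind = "M8", lnL = -1000, n_free_params = 6),
                  class = "codon_fit")
  r <- lrt(f1, f2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  f3 <- structure(list(kind = "M8", lnL = -998.08, n_free_params = 5),
                  class = "codon_fit")
  r2 <- lrt(f1, f3)
  expect_equal(r2$statistic, 3.84, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.050, tolerance = 0.01)
  expect_error(lrt(f2, f1), "more free parameters")
  f4 <- structure(list(kind = "M8", lnL = -1001, n_free_params = 6),
                  class = "codon_fit")
  expect_warning(r3 <- lrt(f1, f4), "clamped")
  expect_equal(r3$statistic, 0)
})

test_that("degenerate identical-sequence alignments are flagged", {
  m <- matrix(rep(c("ATG", "GCT", "CCA"), each = 4), nrow = 4)
  rownames(m) <- paste0("t", 1:4)
  tr <- simulate_tree(4, seed = 2)
  expect_warning(
    f <- fit_codon_model(codon_alignment(m), tr, "M0", n_restarts = 0),
    "unidentifiable")
  expect_true(f$degenerate)
  expect_lt(f$scale, 0.01)
})

test_that("M0 fits recover the simulating dN/dS", {
  tr <- simulate_tree(12, seed = 4)
  sim <- simulate_codon_alignment(tr, site_class_model("M0", omega = 0.3),
                                  200, seed = 6, kappa = 2)
  f <- fit_codon_model(sim$alignment, tr, "M0", n_restarts = 1)
  expect_true(f$convergence)
  expect_gt(f$model$params$omega, 0.2)
  expect_lt(f$model$params$omega, 0.4)
  expect_gt(f$kappa, 1.4)
  expect_lt(f$kappa, 2.8)
})

test_that("branch models recover and flag an elevated foreground", {
  tr <- simulate_tree(12, seed = 31)
  # foreground = the first two-tip clade (a cherry) in the tree
  ntip <- length(tr$tip.label)
  cherry <- NULL
  for (v in (ntip + 1):max(tr$edge)) {
    d <- omegascan:::clade_descendants(tr, v)
    if (length(d) == 2 && all(d <= ntip)) { cherry <- d; break }
  }
  fg_tips <- tr$tip.label[cherry]
  spec <- branch_classes(tr, list(fg = fg_tips))
  sim <- simulate_codon_alignment(
    tr, site_class_model("M0", omega = 0.4), 300, seed = 32,
    branch_spec = spec, branch_omegas = c(0.4, 1.5))
  f <- fit_codon_model(sim$alignment, tr, "M0", branch_spec = spec,
                       n_restarts = 1)
  rep <- branch_dnds_report(f)
  expect_equal(nrow(rep), 2L)
  expect_lt(rep$omega[rep$class == "background"], 1)
  expect_gt(rep$omega[rep$class == "fg"],
            rep$omega[rep$class == "background"])
  expect_true(rep$positive_selection[rep$class == "fg"])
  # single-class report equals the M0 fit
  f0 <- fit_codon_model(sim$alignment, tr, "M0", n_restarts = 0)
  rep0 <- branch_dnds_report(f0)
  expect_equal(nrow(rep0), 1L)
  expect_equal(rep0$omega, f0$model$params$omega)
  # class with zero branches is rejected at validation
  bad <- spec
  bad[bad == 1L] <- 0L
  expect_error(fit_codon_model(sim$alignment, tr, "M0", branch_spec = bad,
                               n_restarts = 0), "zero member branches")
})

test_that("marginal ancestral states match brute-force posteriors", {
  pi <- uniform_pi()
  tr <- ape::read.tree(text = "((A:0.2,B:0.35):0.15,C:0.4);")
  sim <- simulate_codon_alignment(tr, site_class_model("M0", omega = 0.5),
                                  5, seed = 41)
  f <- suppressWarnings(
    fit_codon_model(sim$alignment, tr, "M0", pi = pi, n_restarts = 0,
                    optimize_scale = FALSE, control = list(maxit = 0)))
  # evaluate at fixed parameters so the oracle can use the same ones
  f$kappa <- 2; f$scale <- 1
  f$model <- site_class_model("M0", omega = 0.5)
  states <- codon_state_matrix(sim$alignment, taxa = tr$tip.label)
  asr <- marginal_ancestral_states(f)
  for (s in 1:5) {
    oracle <- oracle_posterior_3taxa(states[, s], 2, 0.5, pi,
                                     0.2, 0.35, 0.15, 0.4)
    expect_lt(max(abs(asr$posterior["node_4", , s] - oracle$root)), 1e-10)
    expect_lt(max(abs(asr$posterior["node_5", , s] - oracle$inner)), 1e-10)
  }
})

test_that("ancestral reconstruction handles consensus and all-missing sites", {
  tr <- simulate_tree(6, seed = 51, height = 0.05)
  m <- matrix("ATG", nrow = 6, ncol = 3, dimnames = list(tr$tip.label, NULL))
  m[, 3] <- NA
  aln <- codon_alignment(m)
  pi <- uniform_pi()
  f <- suppressWarnings(fit_codon_model(aln, tr, "M0", pi = pi,
                                        n_restarts = 0))
  f$kappa <- 2; f$scale <- 1; f$model <- site_class_model("M0", omega = 0.4)
  asr <- marginal_ancestral_states(f)
  expect_true(all(asr$map_codon[, 1:2] == "ATG"))
  expect_true(all(asr$map_prob[, 1:2] > 0.99))
  # all-missing column: posterior equals the prior pi
  expect_lt(max(abs(asr$posterior[1, , 3] - pi)), 1e-9)
  # gap character: all-missing column reconstructed absent at the root
  expect_false(asr$present["node_7", 3])
})
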