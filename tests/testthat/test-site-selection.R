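test_that("posterior arithmetic: one class and two-class toys", {
  # M0: every site's mean omega equals the single class omega
  ll <- matrix(log(c(0.2, 0.05, 0.3)), nrow = 1)
  f <- toy_fit(ll, omegas = 0.37, props = 1)
  f$kind <- "M0"
  post <- site_posteriors(f)
  expect_true(all(post$omega_bar == 0.37))
  expect_true(all(post$pp_positive == 0))

  # two classes, equal proportions, site likelihoods 0.3 / 0.1
  ll2 <- matrix(log(c(0.3, 0.1)), nrow = 2)
  f2 <- toy_fit(ll2, omegas = c(0.2, 2), props = c(0.5, 0.5))
  post2 <- site_posteriors(f2)
  expect_equal(post2$post_1, 0.75)
  expect_equal(post2$post_2, 0.25)
  expect_equal(post2$omega_bar, 0.75 * 0.2 + 0.25 * 2)
  expect_equal(post2$pp_positive, 0.25)
})

test_that("posteriors sum to one and separate simulated site classes", {
  tr <- simulate_tree(16, seed = 61)
  m8 <- site_class_model("M8", p = 2, q = 5, p0 = 0.7, omega_s = 4, k = 5)
  sim <- simulate_codon_alignment(tr, m8, 200, seed = 62)
  f <- suppressWarnings(
    fit_codon_model(sim$alignment, tr, "M8", k = 5, n_restarts = 0))
  post <- site_posteriors(f)
  pcols <- grep("^post_", names(post))
  expect_lt(max(abs(rowSums(post[, pcols]) - 1)), 1e-9)
  is_sel <- sim$truth$site_class == 6  # the omega_s class
  expect_gt(mean(post$pp_positive[is_sel]), mean(post$pp_positive[!is_sel]))
  # rank separation: selected sites dominate the top of the PP ranking
  expect_gt(mean(rank(post$pp_positive)[is_sel]),
            mean(rank(post$pp_positive)[!is_sel]))
})

test_that("conservation index transform clamps at neutrality", {
  expect_equal(conservation_index(0), 1)
  expect_equal(conservation_index(1.50), 0)
  expect_equal(conservation_index(0.44), 0.56)
  expect_equal(conservation_index(1), 0)
  # vector + monotonicity + range
  x <- seq(0, 3, by = 0.01)
  ci <- conservation_index(x)
  expect_true(all(ci >= 0 & ci <= 1))
  expect_true(all(diff(ci) <= 0))
  expect_true(all(ci[x >= 1] == 0))
  # accepts a site_posterior table
  df <- data.frame(site = 1:2, omega_bar = c(0.3, 1.2),
                   pp_positive = c(0, 1))
  class(df) <- c("site_posterior", "data.frame")
  expect_equal(conservation_index(df), c(0.7, 0))
  expect_error(conservation_index(-0.1), ">= 0")
})

test_that("positive-site flags respect thresholds and boundaries", {
  post <- data.frame(site = 1:4, omega_bar = c(0.2, 1.5, 2, 0.9),
                     pp_positive = c(0, 0.97, 0.3, 0.96))
  out <- flag_positive_sites(post, 0.95)
  expect_equal(out$site, c(2, 4))
  expect_equal(nrow(flag_positive_sites(
    transform(post, pp_positive = 0), 0.95)), 0L)
  expect_equal(nrow(flag_positive_sites(post, 1.0)), 0L)
  expect_error(flag_positive_sites(post, 0), "threshold")
})

test_that("column classification follows the property partition", {
  aa <- cbind(rep("A", 5),
              c("V", "I", "V", "V", "I"),
              c("D", "K", "D", "D", "D"),
              c("A", "A", NA, "A", "A"),
              rep(NA_character_, 5))
  rownames(aa) <- paste0("t", 1:5)
  cls <- classify_columns(aa)
  expect_equal(as.character(cls),
               c("unchanged", "conservative", "variable", "unchanged",
                 "undetermined"))
  # permuting rows never changes classes
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(5)
    expect_equal(as.character(classify_columns(aa[perm, ])),
                 as.character(cls))
  }
  # partition is exhaustive and exclusive over determined columns
  set.seed(9)
  rnd <- matrix(sample(unlist(aa_property_groups()), 200, replace = TRUE),
                nrow = 10)
  expect_false(any(is.na(classify_columns(rnd))))
  # tolerance admits m deviants
  one_dev <- matrix(c(rep("A", 9), "K"), ncol = 1)
  expect_equal(as.character(classify_columns(one_dev)), "variable")
  expect_equal(as.character(classify_columns(one_dev, tolerance = 1)),
               "unchanged")
})

test_that("residue composition reports percentages and P+Q", {
  rc <- residue_composition("PPQQ")
  expect_equal(unname(rc$full["P"]), 50)
  expect_equal(unname(rc$full["Q"]), 50)
  expect_equal(rc$pq_percent$full, 100)
  rc2 <- residue_composition("ACDE")
  expect_equal(unname(rc2$full["P"] + rc2$full["Q"]), 0)
  # 100-residue fixture with exactly 14 prolines
  set.seed(10)
  base <- sample(setdiff(unlist(aa_property_groups()), "P"), 86,
                 replace = TRUE)
  seq100 <- paste0(sample(c(base, rep("P", 14))), collapse = "")
  rc3 <- residue_composition(seq100, region = c(1, 50))
  expect_equal(unname(rc3$full["P"]), 14.0)
  expect_error(residue_composition("ACDE", region = c(2, 9)), "region")
})

test_that("candidate site ranking keeps conserved sites in CI order", {
  prof <- data.frame(site = 1:5,
                     ci = c(0.8, 0.9, 0.2, 0.7, 0.9),
                     class = c("unchanged", "unchanged", "variable",
                               "conservative", "variable"))
  out <- candidate_disease_sites(prof)
  expect_equal(out$site, c(2, 1, 4))
  all_var <- transform(prof, class = "variable")
  expect_equal(nrow(candidate_disease_sites(all_var)), 0L)
})

test_that("strong purifying blocks dominate the candidate ranking", {
  tr <- simulate_tree(16, seed = 71)
  cons <- simulate_codon_alignment(tr, site_class_model("M0", omega = 0.05),
                                   40, seed = 72)
  rest <- simulate_codon_alignment(tr, site_class_model("M0", omega = 0.8),
                                   160, seed = 73)
  aln <- codon_alignment(cbind(cons$alignment$codons, rest$alignment$codons))
  f <- suppressWarnings(
    fit_codon_model(aln, tr, "M8", k = 5, n_restarts = 0))
  prof <- conservation_profile(f)
  cand <- candidate_disease_sites(prof)
  top <- cand$site[seq_len(ceiling(nrow(cand) / 10))]
  expect_gt(mean(top <= 40), 0.8)
  # profile invariants
  expect_true(all(prof$ci[prof$omega_bar >= 1] == 0))
  expect_true(all(prof$ci >= 0 & prof$ci <= 1))
})

test_that("false-positive rate under the null stays low", {
  # M7-simulated data (all omega < 1): flagged sites are rare
  tr <- simulate_tree(12, seed = 81)
  frac <- numeric(5)
  for (r in 1:5) {
    sim <- simulate_codon_alignment(tr, site_class_model("M7", p = 2, q = 5,
                                                         k = 5),
                                    150, seed = 500 + r)
    f <- suppressWarnings(
      fit_codon_model(sim$alignment, tr, "M8", k = 5, n_restarts = 0))
    fl <- flag_positive_sites(site_posteriors(f), 0.95)
    frac[r] <- nrow(fl) / 150
  }
  expect_lt(mean(frac), 0.05)
})
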