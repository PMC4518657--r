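test_that("Kozak context classification follows the purine rules", {
  # pyrimidine at -3 and +4 -> weak
  tt <- scan_tis("CCCTTTATGCTTTTT")
  expect_equal(tt$position, 7L)
  expect_equal(tt$context, "weak")
  # A at -3, G at +4 -> strong
  tt2 <- scan_tis("CCCATTATGGTTTTT")
  expect_equal(tt2$context, "strong")
  # classification depends only on the -3 and +4 bases
  set.seed(3)
  nt <- c("A", "C", "G", "T")
  for (i in 1:30) {
    m3 <- sample(nt, 1); p4 <- sample(nt, 1)
    s <- paste0(paste0(sample(nt, 5, TRUE), collapse = ""),
                m3, paste0(sample(c("C", "T"), 2, TRUE), collapse = ""),
                "ATG", p4, paste0(sample(nt, 6, TRUE), collapse = ""))
    hit <- scan_tis(s)
    hit <- hit[hit$position == 9, ]
    expect_equal(hit$context,
                 if (m3 %in% c("A", "G") && p4 %in% c("A", "G"))
                   "strong" else "weak")
  }
  # missing upstream context -> weak, undetermined -3
  tt3 <- scan_tis("ATGGGGTTT")
  expect_true(is.na(tt3$minus3[1]))
  expect_equal(tt3$context[1], "weak")
  expect_equal(nrow(scan_tis("CCCCCC")), 0L)
})

test_that("open-frame filter picks the first usable ATG as primary", {
  s <- paste0("CCCATGTAAATGGGG", strrep("GGC", 10), "TGA")
  tt <- scan_tis(s, cds_end = nchar(s))
  expect_equal(tt$position[1:2], c(4L, 10L))
  expect_false(tt$open_frame[1])   # immediate TAA
  expect_true(tt$open_frame[2])
  expect_equal(tt$primary, c(FALSE, TRUE))
})

test_that("polyadenylation scanning reports exact 1-based spans", {
  set.seed(5)
  utr <- paste0(sample(c("C", "G"), 200, TRUE), collapse = "")
  substr(utr, 129, 134) <- "AATAAA"
  hits <- scan_polya(utr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 129L)
  expect_equal(hits$end, 134L)
  expect_equal(hits$motif, "AATAAA")
  expect_equal(hits$ps, "PS1")
  expect_equal(nrow(scan_polya(strrep("CG", 50))), 0L)
  # trailing poly(A) tail does not change the calls within the UTR
  hits2 <- scan_polya(paste0(utr, strrep("A", 50)))
  expect_equal(hits2[hits2$start <= 200, ], hits)
  expect_true(all(hits$end <= 200))
})

test_that("human-like planted polyA fixture is recovered exactly", {
  fx <- make_gene_fixture(seed = 7)
  hits <- scan_polya(fx$gene$utr3)
  expect_equal(nrow(hits), 5L)
  expect_equal(hits$start, fx$truth$polya$start)
  expect_equal(hits$end, fx$truth$polya$end)
  expect_equal(hits$motif, fx$truth$polya$motif)
  expect_equal(hits$ps, paste0("PS", 1:5))
})

test_that("Fitch ancestral presence matches hand-worked and brute-force cases", {
  tr8 <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  tips <- function(v) {
    m <- matrix(v, ncol = 1,
                dimnames = list(c("A","B","C","D","E","F","G","H"), "f"))
    m
  }
  # present in all leaves -> present everywhere
  ap <- ancestral_presence(tips(rep(TRUE, 8)) , tr8)
  expect_true(all(ap$node_states == "present"))
  # present in a single leaf -> root absent (single gain)
  ap1 <- ancestral_presence(tips(c(TRUE, rep(FALSE, 7))), tr8)
  expect_equal(unname(ap1$root), "absent")
  expect_equal(ap1$score, 1L)
  # two all-present sister cherries on one side, rest absent -> root ambiguous
  v <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  ap2 <- ancestral_presence(tips(v), tr8)
  expect_equal(unname(ap2$root), "ambiguous")
  # brute-force equivalence on random characters
  set.seed(11)
  for (i in 1:20) {
    v <- sample(c(0L, 1L), 8, replace = TRUE)
    fp <- omegascan:::fitch_parsimony(tr8, matrix(v, ncol = 1,
      dimnames = list(c("A","B","C","D","E","F","G","H"), NULL)))
    oracle <- oracle_fitch_root(tr8, v)
    expect_equal(fp$score, oracle$score)
    want <- if (length(oracle$root) == 2) "ambiguous" else
      as.character(oracle$root)
    expect_equal(unname(fp$root), want)
  }
  expect_error(ancestral_presence(tips(rep(TRUE, 8))[1:7, , drop = FALSE],
                                  tr8), "match")
})

test_that("exon-duplication detector finds planted copies, skips noise", {
  set.seed(13)
  nt <- c("A", "C", "G", "T")
  tmpl <- paste0(sample(nt, 39, TRUE), collapse = "")
  rand <- function(n) paste0(sample(nt, n, TRUE), collapse = "")
  # one exact copy with splice context
  intron <- paste0(rand(80), "AG", tmpl, "GT", rand(60))
  hits <- detect_exon_duplications(intron, tmpl)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$length, 39L)
  expect_equal(hits$start, 83L)
  expect_true(hits$splice_ag_upstream)
  expect_true(hits$splice_gt_downstream)
  # random intron: nothing above threshold
  for (i in 1:20) {
    empty <- detect_exon_duplications(rand(400), tmpl, 0.8)
    expect_equal(nrow(empty), 0L)
  }
  expect_error(detect_exon_duplications(rand(100), "ATGATGA"), "10 nt")
})

test_that("multiple degraded copies are recovered non-overlapping", {
  set.seed(17)
  nt <- c("A", "C", "G", "T")
  tmpl <- paste0(sample(nt, 39, TRUE), collapse = "")
  degrade <- function(s, nmut) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(39, nmut)
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(nt, b), 1), "")
    paste0(ch, collapse = "")
  }
  rand <- function(n) paste0(sample(nt, n, TRUE), collapse = "")
  copies <- vapply(c(2, 3, 5, 6), function(nm) degrade(tmpl, nm), "")
  intron <- paste0(rand(50), copies[1], rand(40), copies[2], rand(40),
                   copies[3], rand(40), copies[4], rand(50))
  hits <- detect_exon_duplications(intron, tmpl, 0.8)
  expect_equal(nrow(hits), 4L)
  expect_true(all(hits$identity >= 0.84))
  expect_true(all(diff(hits$start) >= 39))
  # recall is perfect for copies >= threshold + 0.05
  expect_equal(hits$start, c(51L, 130L, 209L, 288L))
})

test_that("gene fixtures plant recoverable TIS layouts", {
  # weak exon-1 TIS + strong exon-2 TIS, exon-1 ATG primary
  fx <- make_gene_fixture(tis = "weak1_strong2", seed = 19)
  gm <- fx$gene
  mrna_cds_end <- nchar(gm$utr5) + nchar(gm$cds)
  tt <- scan_tis(paste0(gm$utr5, gm$cds), cds_end = mrna_cds_end)
  p1 <- fx$truth$tis$exon1$position
  p2 <- fx$truth$tis$exon2$position
  expect_true(all(c(p1, p2) %in% tt$position))
  expect_equal(tt$context[tt$position == p1], "weak")
  expect_equal(tt$context[tt$position == p2], "strong")
  expect_true(tt$primary[tt$position == p1])

  # marsupial-like: single TIS in exon 2
  fx2 <- make_gene_fixture(tis = "exon2_only", seed = 23)
  tt2 <- scan_tis(paste0(fx2$gene$utr5, fx2$gene$cds),
                  cds_end = nchar(fx2$gene$utr5) + nchar(fx2$gene$cds))
  p <- fx2$truth$tis$exon2$position
  expect_equal(tt2$context[tt2$position == p], "strong")
  expect_true(tt2$primary[tt2$position == p])

  # bovine-like: extra upstream strong ATG becomes primary
  fx3 <- make_gene_fixture(tis = "extra_strong1", seed = 29)
  tt3 <- scan_tis(paste0(fx3$gene$utr5, fx3$gene$cds),
                  cds_end = nchar(fx3$gene$utr5) + nchar(fx3$gene$cds))
  pe <- fx3$truth$tis$extra_exon1$position
  expect_equal(tt3$context[tt3$position == pe], "strong")
  expect_true(tt3$primary[tt3$position == pe])
})

test_that("planted exon-7 duplications in fixtures are recovered", {
  fx <- make_gene_fixture(n_exon7_copies = 2, seed = 31)
  hits <- detect_exon_duplications(fx$truth$dup_region, fx$truth$exon7)
  expect_equal(hits$start, fx$truth$duplications$start)
  expect_true(all(hits$identity == 1))
  expect_true(all(hits$splice_ag_upstream & hits$splice_gt_downstream))
  # horse-like multiplicity with degraded copies
  fx6 <- make_gene_fixture(n_exon7_copies = 6, copy_identity = 0.9,
                           seed = 37)
  hits6 <- detect_exon_duplications(fx6$truth$dup_region, fx6$truth$exon7,
                                    0.8)
  expect_equal(nrow(hits6), 6L)
  expect_equal(hits6$start, fx6$truth$duplications$start)
})

test_that("pseudogene diagnostics spot stops and frameshifts", {
  clean <- paste0("ATG", strrep("GCT", 20), "TGA")
  d <- pseudogene_diagnostics(clean)
  expect_false(d$pseudogene)
  stopmut <- paste0("ATG", strrep("GCT", 5), "TAA", strrep("GCT", 14), "TGA")
  d2 <- pseudogene_diagnostics(stopmut)
  expect_equal(d2$premature_stops, 7L)
  expect_true(d2$pseudogene)
  shifted <- paste0("ATG", "G", strrep("GCT", 20), "TGA")
  expect_true(pseudogene_diagnostics(shifted)$frameshifted)
})
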