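---
title: "Codon-model selection scans: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection scans: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements, the defaults it chose where the design was genuinely open,
and what its validation does and does not demonstrate.

## The substitution model

All likelihoods are computed under the Goldman–Yang codon model on the
61 sense codons of the standard genetic code. The instantaneous rate
from codon *i* to codon *j* is zero unless the codons differ at exactly
one nucleotide position (and neither is a stop); single-nucleotide
changes get rate

\[ q_{ij} = \pi_j \times \{1,\ \kappa,\ \omega,\ \omega\kappa\} \]

for synonymous transversions, synonymous transitions, nonsynonymous
transversions and nonsynonymous transitions respectively. The generator
is rescaled so that the mean substitution rate at stationarity is one;
branch lengths are therefore expected substitutions per codon. κ is the
transition/transversion rate ratio (default start 2); ω = dN/dS is the
object of inference: below 1 purifying selection, 1 neutrality, above 1
positive selection.

Equilibrium frequencies default to **F3x4** (products of positional
nucleotide frequencies, renormalized over sense codons); **F61**
(empirical codon frequencies) is available. Either way, zero frequencies
are floored at 1e-8 and renormalized so that no codon is unreachable —
important for small alignments where F61 would otherwise put exact zeros
on unobserved codons.

## Site-class mixtures and branch models

Three site models are fitted:

* **M0** — one ω shared by all sites and branches (3 free parameters
  with the branch-length scale: κ, ω, scale).
* **M7** — ω ~ Beta(p, q) on (0, 1), the "nearly neutral" model.
* **M8** — a fraction p0 of sites from Beta(p, q) plus a fraction
  1 − p0 at ω_s ≥ 1, the positive-selection alternative.

The beta is discretized into K = 10 equal-probability categories
represented by their **medians**, the convention of the mainstream
codon-model software this package mirrors; K is an argument. M7 vs M8 is
a nested comparison with 2 degrees of freedom.

**Branch (multi-ratio) models** attach one ω to each branch class:
class 0 is the background, and each configured foreground clade (stem
branch plus all branches inside the clade) gets its own ω. These combine
with the single-class site model only; branch–site combinations are out
of scope. The pipeline can also *screen* for foregrounds: each terminal
branch gets a quick two-ratio fit and branches whose ω exceeds a cutoff
(default 0.6) are proposed — a coarse device mirroring the practice of
choosing foreground lineages whose lineage-wise dN/dS looks elevated in
a preliminary reconstruction.

All LRTs use the plain χ² reference with df equal to the difference in
free parameter counts. For M7-vs-M8 the null places p0 on the boundary,
which makes the χ²(2) reference conservative; no boundary-mixture
correction is applied, matching common practice. The test-size check in
the test suite accordingly allows the empirical rejection rate at
nominal 5% to be anywhere up to 10%, and in practice observes it well
below the nominal level.

## Likelihood computation and optimization

Per-site likelihoods come from Felsenstein pruning over the codon
alphabet, implemented in C++ (RcppArmadillo) with per-site rescaling to
avoid underflow on deep trees. Transition matrices are built by
eigendecomposition of the symmetrized reversible generator
(P(t) = U e^{Λt} U⁻¹); if flooring has made that decomposition
ill-conditioned (reconstruction error above 1e-6) the code falls back to
`Matrix::expm`. Missing codon states (alignment gaps, ambiguity codes,
masked stops) enter the pruning as partial-likelihood vectors of ones,
so a fully missing row is exactly uninformative — the package treats
missing data as unknown states rather than as evidence.

Optimization is box-constrained L-BFGS-B on transformed parameters:
log(κ), log(ω), log(p), log(q), logit(p0), and ω_s = 1 + e^z so the
selection class respects its ω_s ≥ 1 boundary. Branch lengths are by
default the input tree's values multiplied by one free scale factor —
the robust, fast choice when the tree comes from an independent
nucleotide analysis; full per-branch optimization exists behind
`optimize_branch_lengths = TRUE` (slow path, intended for small trees).
Fits start from κ = 2, ω = 0.4, Beta(1, 1), p0 = 0.9, ω_s = 2 and add
`n_restarts = 2` randomly jittered restarts by default; parameters
landing within 1e-3 of a box bound are flagged. An alignment with no
variable columns is reported degenerate: ω is unidentifiable and the
scale collapses toward zero, with a warning rather than silence.

## Empirical-Bayes site inference and the conservation index

Site posteriors default to **NEB**: P(k | site) ∝ prop_k · L(site | ω_k)
at the MLEs, giving each site its posterior mean ω̄ and the posterior
probability of the ω > 1 class(es). A **BEB-style mode** integrates over
a 10×10×10 grid on (p0, beta mean, ω_s) — with the beta precision p + q,
κ, frequencies and branch lengths held at their MLEs, a uniform grid
prior, and grid points weighted by their marginal likelihood. NEB is the
default because it is exact at the MLEs and cheap; BEB matters when the
mixture parameters are poorly determined. The difference is documented
as a deviation from analyses that report BEB only.

The **conservation index** is CI = 1 − ω̄, truncated to exactly 0 for
ω̄ ≥ 1, so neutral and positively selected sites score zero and strongly
constrained sites approach one. Column classes use the amino-acid view:
*unchanged* (one residue state), *conservative* (all states within one
chemical property group), *variable*. The default property partition is
{AVLIMC} {FWY} {KRH} {DE} {STNQ} {G} {P}: glycine and proline are
singletons because both are structurally exceptional — a consideration
that matters in proline-rich extracellular matrix proteins, where P is a
large fraction of the sequence. The partition is an argument, and a
tolerance parameter can forgive up to m deviant sequences per column
(default 0: strict). Candidate mutation-sensitive sites are the
unchanged/conservative columns ranked by CI (ties by position) — the
positions where a substitution is most likely to disrupt function.

## Ancestral reconstruction

Marginal ancestral states are exact per-node posteriors from an up–down
pass, mixed over site classes with each site's empirical-Bayes class
weights. Gap/missing presence is reconstructed separately as a binary
character under Fitch parsimony with ties resolved toward presence (a
deletion is the marked event). Fitch is also the engine for ancestral
presence of polyadenylation signals; ties there are reported as
`ambiguous`, never guessed. Dollo-style reasoning was considered for
polyA characters but Fitch is the default because gains and losses of a
hexamer are both single-nucleotide events with no strong asymmetry.

## Gene-feature scanners

* **Kozak/TIS**: every ATG is reported with the bases at −3 and +4;
  strong ⟺ both purines. An ATG with fewer than 3 upstream bases has an
  undetermined context and classes as weak. With an annotated CDS end,
  the open-frame flag requires translation to reach it without an
  in-frame stop, and the 5'-most open ATG is primary — encoding the
  observation that prediction tools pick the first usable start.
* **Polyadenylation**: all AATAAA and ATTAAA occurrences, 1-based spans
  with position 1 the first base after the stop codon (the convention
  that reproduces published UTR span tables); signals numbered PS1… in
  positional order.
* **Exon duplication**: ungapped sliding-window identity of the template
  exon against an intron, greedy non-overlapping selection above the
  identity threshold (default 0.8), with AG/GT splice-context flags.
  Gapped alignment is deliberately not used: the biological signature
  being detected is same-length, near-identical tandem copies.

## The synthetic-data generator

The simulator is the package's source of ground truth: Yule trees
rescaled to a target height, codon columns assigned to ω classes by the
model's proportions, root codons from π, and branch evolution by direct
sampling from P(t) (a Gillespie jump-chain mode logs every substitution
with its syn/nonsyn status for event-count audits). Pseudogenization
injects nonsense substitutions and 1–2 nt indels at per-codon rates into
flagged lineages, with a complete event log. Gene fixtures emit a
13-exon gene with planted TIS contexts, 3'UTR hexamers at requested
offsets, and 39-bp copies of exon 7 in the downstream intron, plus a
truth table for exact comparison.

Defaults describe the study system the package targets: 53 functional
taxa, 447 codons, and a tree height of 2 expected substitutions per
codon (root-to-tip), a mammal-depth calibration for a fast-evolving
secreted protein over roughly 220 My — at near-neutral synonymous rates
that depth corresponds to a root-to-tip dS of about 0.7 per site. The
generator emulates among-site and among-branch ω variation, missing
data, and pseudogene lesions; it does **not** emulate alignment error,
context-dependent mutation, indel-length tails, GC-biased gene
conversion, or lineage effects correlated with life history. Passing
recovery tests therefore demonstrates correctness of the inference
machinery under the model's own assumptions, not robustness to the
model violations real alignments carry.

## Problem sizes and numerical choices in the validation

The test suite chooses problem sizes as a compromise between statistical
resolution and a test run a developer will actually execute: one-ratio
recovery uses 24 taxa × 500 codons × 5 seeds per ω; the M8 ω_s recovery
check uses the median error over 3 seeds at 500 codons (a single seed's
ω_s estimate is noisy when only ~10% of sites carry the signal); the
test-size audit runs 50 null replicates at 12 taxa × 150 codons with
K = 5 and no restarts (the null surface is smooth; restarts change
nothing but the runtime); oracle comparisons run at 3–4 taxa where
internal-state enumeration is exact. Tolerances: pruning vs enumeration
1e-8; stochastic-matrix and stationarity identities 1e-10; M8→M7
collapse 1e-6.

One validation outcome is reported honestly rather than engineered away:
with only 5 truly positive codons at ω = 3 among 400 nearly neutral
sites, the M8 maximum-likelihood solution prefers to absorb those sites
into a moderate shared selection class rather than isolate them
(the merged solution's lnL exceeds the truth-parameter configuration),
and no site reaches posterior probability 0.95 under NEB or the BEB
grid. Detecting a handful of positively selected sites at this contrast
needs either more sites in the selection class or stronger per-site
signal than these conditions provide; the corresponding recovery test
documents this limit of empirical-Bayes site detection at small p1.

## Known limitations

Single genetic code (the code table is a hook, untested elsewhere);
reversible models only (likelihood is root-invariant, so rooting matters
only for ancestral states); no branch–site models; no codon models with
selection on amino-acid properties; the BEB grid holds nuisance
parameters at their MLEs rather than integrating them; the foreground
screen refits one branch at a time and is a heuristic, not an inference.
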