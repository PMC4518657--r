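Package: omegascan
Title: Codon-Model Selection Scans and Gene-Feature Profiling for
    Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood-based analysis of selective constraint in
    protein-coding gene alignments. Implements Goldman-Yang codon
    substitution models with site-class mixtures (M0, M7, M8) and
    multi-ratio branch models, likelihood-ratio tests for positive
    selection, empirical-Bayes per-site posteriors, a conservation-index
    transform for predicting mutation-sensitive positions, and marginal
    ancestral sequence reconstruction. Also provides gene-feature
    scanners (Kozak translation-initiation context, polyadenylation
    hexamers with ancestral-presence parsimony, tandem exon-duplication
    detection) and a codon-alignment simulator with site/branch
    dN/dS regimes and pseudogenized lineages for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
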