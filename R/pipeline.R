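# End-to-end orchestration: a selection scan (model fits, LRT table,
# per-site conservation profile) and a gene-feature report, both driven
# by a validated config and writing TSV + JSON bundles.

#' Build and validate a run configuration
#'
#' @param alignment Path to a codon-aligned FASTA (or a
#'   [codon_alignment()] object).
#' @param tree Path to a Newick tree (or an [ape::phylo]).
#' @param models Site models to fit, subset of `c("M0", "M7", "M8")`.
#' @param foreground Named list of tip-label vectors defining branch
#'   ratio classes for branch-model fits (optional).
#' @param reference Optional reference taxon for coordinate projection.
#' @param pp_threshold Positive-site posterior cutoff (default 0.95).
#' @param min_identity Exon-duplication identity threshold (default 0.8).
#' @param auto_foreground_cutoff If not `NULL`, branches whose
#'   preliminary single-branch dN/dS exceeds this cutoff (each estimated
#'   by a one-off two-ratio fit) are proposed as additional foreground
#'   classes. Default `NULL` (off).
#' @param k Beta categories (default 10).
#' @param n_restarts Optimizer restarts (default 2).
#' @param seed Seed for all stochastic steps.
#' @param outdir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(alignment, tree, models = c("M0", "M7", "M8"),
                       foreground = NULL, reference = NULL,
                       pp_threshold = 0.95, min_identity = 0.8,
                       auto_foreground_cutoff = NULL, k = 10,
                       n_restarts = 2, seed = 1, outdir = tempfile("scan")) {
  if (length(models) == 0) stop("empty model list")
  bad <- setdiff(models, c("M0", "M7", "M8"))
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "))
  if (pp_threshold <= 0 || pp_threshold >= 1)
    stop("pp_threshold must be in (0, 1)")
  if (min_identity < 0 || min_identity > 1)
    stop("min_identity must be in [0, 1]")
  structure(list(alignment = alignment, tree = tree, models = models,
                 foreground = foreground, reference = reference,
                 pp_threshold = pp_threshold, min_identity = min_identity,
                 auto_foreground_cutoff = auto_foreground_cutoff,
                 k = k, n_restarts = n_restarts, seed = seed,
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

load_inputs <- function(config) {
  aln <- config$alignment
  if (is.character(aln)) aln <- read_codon_alignment(aln)
  tree <- config$tree
  if (is.character(tree)) tree <- read_newick(tree)
  if (!is.null(config$reference))
    aln <- project_to_reference(aln, config$reference)
  list(aln = aln, tree = tree)
}

#' Run a full selection scan
#'
#' Fits the configured site models (and branch models for each
#' configured foreground clade), assembles the LRT table (each
#' alternative against its nested null: M8 vs M7, branch models vs M0),
#' computes the per-site conservation profile under the richest fitted
#' site model, and writes `lrt_table.tsv`, `site_profile.tsv` and
#' `report.json` into the output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fits`, `lrt_table`, `profile`,
#'   `branch_report`, and the output paths.
#' @export
run_selection_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  inp <- load_inputs(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  fits <- list()
  for (m in config$models) {
    message("fitting ", m)
    fits[[m]] <- with_stage(paste0("fit_", m), fit_codon_model(
      inp$aln, inp$tree, model = m, k = config$k,
      n_restarts = config$n_restarts))
  }
  foreground <- config$foreground
  if (!is.null(config$auto_foreground_cutoff) && "M0" %in% names(fits)) {
    auto <- auto_foreground(inp$aln, inp$tree, fits[["M0"]],
                            config$auto_foreground_cutoff,
                            config$n_restarts)
    foreground <- c(foreground, auto[setdiff(names(auto), names(foreground))])
  }
  branch_fits <- list()
  if (!is.null(foreground) && length(foreground)) {
    for (nm in names(foreground)) {
      spec <- branch_classes(inp$tree, foreground[nm])
      branch_fits[[nm]] <- with_stage(paste0("branch_", nm), fit_codon_model(
        inp$aln, inp$tree, model = "M0", branch_spec = spec,
        k = config$k, n_restarts = config$n_restarts))
    }
  }

  lrt_rows <- list()
  if (all(c("M7", "M8") %in% names(fits)))
    lrt_rows[["M7_vs_M8"]] <- lrt(fits$M7, fits$M8)
  if ("M0" %in% names(fits))
    for (nm in names(branch_fits))
      lrt_rows[[paste0("M0_vs_", nm)]] <- lrt(fits$M0, branch_fits[[nm]])
  lrt_table <- do.call(rbind, lapply(names(lrt_rows), function(nm) {
    x <- lrt_rows[[nm]]
    data.frame(comparison = nm, lnL_null = x$lnL_null, lnL_alt = x$lnL_alt,
               statistic = x$statistic, df = x$df, p_value = x$p_value)
  }))
  if (!is.null(lrt_table) && nrow(lrt_table) > 1) {
    branch_rows <- grepl("^M0_vs_", lrt_table$comparison)
    lrt_table$p_holm <- NA_real_
    if (any(branch_rows))
      lrt_table$p_holm[branch_rows] <-
        stats::p.adjust(lrt_table$p_value[branch_rows], "holm")
  }

  profile <- NULL
  site_model_fit <- fits[[intersect(c("M8", "M7", "M0"), names(fits))[1]]]
  if (!is.null(site_model_fit))
    profile <- with_stage("site_profile", conservation_profile(
      site_model_fit, pp_threshold = config$pp_threshold))

  branch_report <- do.call(rbind, lapply(names(branch_fits), function(nm) {
    cbind(model = nm, branch_dnds_report(branch_fits[[nm]]))
  }))

  paths <- list(
    lrt = file.path(config$outdir, "lrt_table.tsv"),
    profile = file.path(config$outdir, "site_profile.tsv"),
    json = file.path(config$outdir, "report.json"))
  if (!is.null(lrt_table))
    utils::write.table(lrt_table, paths$lrt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(profile))
    utils::write.table(profile, paths$profile, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  report <- list(
    config = config_summary(config),
    fits = lapply(fits, fit_summary),
    branch_fits = lapply(branch_fits, fit_summary),
    lrt_table = lrt_table,
    branch_report = branch_report,
    positive_sites = if (!is.null(profile))
      flag_positive_sites(site_posteriors(site_model_fit),
                          config$pp_threshold) else NULL,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, paths$json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(fits = fits, branch_fits = branch_fits,
                 lrt_table = lrt_table, profile = profile,
                 branch_report = branch_report, paths = paths))
}

# preliminary per-branch screen: each terminal/internal branch gets a
# two-ratio fit (that branch vs rest); branches above the cutoff are
# proposed as foregrounds. Deliberately coarse - a screening device.
auto_foreground <- function(aln, tree, m0_fit, cutoff, n_restarts) {
  out <- list()
  for (i in seq_len(length(tree$tip.label))) {
    tip <- tree$tip.label[i]
    spec <- branch_classes(tree, stats::setNames(list(tip), tip))
    f <- try(fit_codon_model(aln, tree, model = "M0", branch_spec = spec,
                             n_restarts = 0), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (f$branch_omegas[2] > cutoff) out[[tip]] <- tip
  }
  out
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

config_summary <- function(config) {
  cfg <- unclass(config)
  cfg$alignment <- if (is.character(cfg$alignment)) cfg$alignment else "<in-memory>"
  cfg$tree <- if (is.character(cfg$tree)) cfg$tree else "<in-memory>"
  cfg
}

fit_summary <- function(fit) {
  list(kind = fit$kind, lnL = fit$lnL, kappa = fit$kappa,
       scale = fit$scale, params = fit$model$params,
       branch_omegas = fit$branch_omegas,
       n_free_params = fit$n_free_params,
       convergence = fit$convergence, at_bound = fit$at_bound)
}

#' Run a gene-feature report over a set of gene models
#'
#' For each gene model: the TIS table (position, -3/+4 context bases,
#' class, open-frame flag, primary call on the spliced mRNA), the
#' polyadenylation table (PS numbering on the 3'UTR), and, when an
#' intron sequence and template exon are supplied, the exon-duplication
#' table. If a tree over the gene names is supplied, polyA signals that
#' are shared across species (matched by PS motif + approximate
#' position) get a Fitch ancestral-presence root state.
#'
#' @param genes Named list of [gene_model()] objects (names = species).
#' @param tree Optional [ape::phylo] over the species names.
#' @param dup_search Optional named list: for each species, a list with
#'   `intron` and `template` sequences for duplication scanning.
#' @param min_identity Duplication identity threshold (default 0.8).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, list with `tis`, `polya`, `duplications`,
#'   `ancestral_polya` tables and output paths.
#' @export
run_feature_report <- function(genes, tree = NULL, dup_search = NULL,
                               min_identity = 0.8, outdir = tempfile("feat")) {
  stopifnot(is.list(genes), !is.null(names(genes)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  species <- names(genes)
  if (!is.null(tree)) species <- intersect(tree$tip.label, species)

  tis_tab <- do.call(rbind, lapply(species, function(sp) {
    gm <- genes[[sp]]
    cds_end_mrna <- nchar(gm$utr5) + nchar(gm$cds)
    tt <- scan_tis(paste0(gm$utr5, gm$cds), cds_end = cds_end_mrna)
    if (nrow(tt)) cbind(species = sp, tt) else NULL
  }))
  polya_tab <- do.call(rbind, lapply(species, function(sp) {
    gm <- genes[[sp]]
    if (!nzchar(gm$utr3)) {
      warning("species ", sp, " has no 3'UTR annotation; skipped")
      return(NULL)
    }
    pt <- scan_polya(gm$utr3)
    if (nrow(pt)) cbind(species = sp, utr3_length = nchar(gm$utr3), pt)
    else NULL
  }))
  dup_tab <- NULL
  if (!is.null(dup_search)) {
    dup_tab <- do.call(rbind, lapply(names(dup_search), function(sp) {
      ds <- dup_search[[sp]]
      ht <- detect_exon_duplications(ds$intron, ds$template, min_identity)
      if (nrow(ht)) cbind(species = sp, ht) else NULL
    }))
  }
  anc <- NULL
  if (!is.null(tree) && !is.null(polya_tab) && nrow(polya_tab)) {
    anc <- ancestral_polya_presence(polya_tab, tree)
  }
  paths <- list(tis = file.path(outdir, "tis_table.tsv"),
                polya = file.path(outdir, "polya_table.tsv"),
                dup = file.path(outdir, "duplication_table.tsv"),
                json = file.path(outdir, "features.json"))
  if (!is.null(tis_tab))
    utils::write.table(tis_tab, paths$tis, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(polya_tab))
    utils::write.table(polya_tab, paths$polya, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(dup_tab))
    utils::write.table(dup_tab, paths$dup, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  jsonlite::write_json(list(tis = tis_tab, polya = polya_tab,
                            duplications = dup_tab,
                            ancestral_polya = anc),
                       paths$json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(tis = tis_tab, polya = polya_tab, duplications = dup_tab,
                 ancestral_polya = anc, paths = paths))
}

# group polyA hits across species into shared signals (same motif, start
# within 30 nt of the group median) and reconstruct root presence
ancestral_polya_presence <- function(polya_tab, tree) {
  polya_tab <- polya_tab[order(polya_tab$start), ]
  groups <- integer(nrow(polya_tab))
  g <- 0L
  centers <- numeric(0); motifs <- character(0)
  for (i in seq_len(nrow(polya_tab))) {
    hit <- FALSE
    for (j in seq_len(g)) {
      if (polya_tab$motif[i] == motifs[j] &&
          abs(polya_tab$start[i] - centers[j]) <= 30) {
        groups[i] <- j; hit <- TRUE; break
      }
    }
    if (!hit) {
      g <- g + 1L
      groups[i] <- g
      centers[g] <- polya_tab$start[i]
      motifs[g] <- polya_tab$motif[i]
    }
  }
  pres <- matrix(FALSE, length(tree$tip.label), g,
                 dimnames = list(tree$tip.label,
                                 paste0("sig", seq_len(g))))
  for (i in seq_len(nrow(polya_tab)))
    pres[polya_tab$species[i], groups[i]] <- TRUE
  ap <- ancestral_presence(pres, tree)
  data.frame(signal = colnames(pres), motif = motifs,
             median_start = vapply(seq_len(g), function(j)
               stats::median(polya_tab$start[groups == j]), numeric(1)),
             root_state = unname(ap$root),
             n_species = colSums(pres))
}
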