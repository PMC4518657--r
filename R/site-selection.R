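# Per-site inference: empirical-Bayes class posteriors, conservation
# index, positive-selection flags, column conservation classes, residue
# composition, and the ranked candidate list of mutation-sensitive sites.

#' Empirical-Bayes site posteriors under a fitted site-class model
#'
#' Naive empirical Bayes (NEB, default) evaluates class posteriors at
#' the MLEs: `P(k | site) ~ prop_k * L(site | omega_k)`. The `"BEB"`
#' method additionally integrates over parameter uncertainty on a
#' discrete grid over (p0, beta mean, selection-class omega) for M8
#' fits, holding kappa, frequencies and the beta precision p+q at their
#' MLEs; the grid prior is uniform and grid points are weighted by their
#' marginal data likelihood.
#'
#' @param fit A `codon_fit` from [fit_codon_model()].
#' @param method `"NEB"` (default) or `"BEB"` (M8 fits only).
#' @param grid_n Grid points per BEB dimension (default 10).
#' @return Data frame of class `site_posterior`: `site`, `omega_bar`
#'   (posterior mean dN/dS), `pp_positive` (posterior mass on classes
#'   with dN/dS > 1), plus one `post_k` column per class.
#' @export
site_posteriors <- function(fit, method = c("NEB", "BEB"), grid_n = 10) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "codon_fit"))
  if (fit$kind == "branch")
    stop("site posteriors require a site-class model fit")
  if (method == "BEB") {
    if (fit$kind != "M8") stop("BEB mode is defined for M8 fits")
    return(site_posteriors_beb(fit, grid_n))
  }
  ll <- fit$class_loglik
  props <- fit$model$props
  omegas <- fit$model$omegas
  post <- class_posterior(ll, props)
  build_site_posterior(post, omegas)
}

class_posterior <- function(ll, props) {
  lw <- log(ifelse(props > 0, props, .Machine$double.xmin)) + ll
  m <- apply(lw, 2L, max)
  w <- exp(lw - rep(m, each = nrow(lw)))
  sw <- colSums(w)
  if (any(sw == 0 | !is.finite(sw)))
    warning("zero total likelihood at site(s) ",
            paste(utils::head(which(sw == 0 | !is.finite(sw)), 5), collapse = ", "),
            "; posteriors undefined there")
  sweep(w, 2L, sw, "/")
}

build_site_posterior <- function(post, omegas) {
  omega_bar <- as.numeric(crossprod(post, omegas))
  pp_pos <- as.numeric(colSums(post[omegas > 1, , drop = FALSE]))
  out <- data.frame(site = seq_len(ncol(post)),
                    omega_bar = omega_bar, pp_positive = pp_pos)
  pm <- t(post)
  colnames(pm) <- paste0("post_", seq_len(nrow(post)))
  out <- cbind(out, as.data.frame(pm))
  class(out) <- c("site_posterior", "data.frame")
  out
}

# BEB-style grid integration for M8: p0 and beta-mean on grid midpoints of
# (0,1), omega_s on midpoints of [1, 11]; p+q fixed at the MLE sum.
site_posteriors_beb <- function(fit, grid_n = 10) {
  prm <- fit$model$params
  nu <- prm$p + prm$q
  k <- fit$k
  mids <- (seq_len(grid_n) - 0.5) / grid_n
  p0_grid <- mids
  mu_grid <- mids
  ws_grid <- 1 + 10 * mids

  states <- codon_state_matrix(fit$aln, taxa = fit$tree$tip.label)
  # distinct omega values: k beta categories per mu, plus the ws grid
  omega_rows <- c(unlist(lapply(mu_grid, function(mu)
    beta_class_omegas(mu * nu, (1 - mu) * nu, k))), ws_grid)
  ll <- class_site_loglik(states, fit$tree, omega_rows, fit$kappa, fit$pi,
                          fit$scale)
  n_site <- ncol(ll)
  # accumulate over the grid
  acc_post <- matrix(0, 2, n_site)       # mass on beta vs selection class
  acc_omega <- numeric(n_site)
  log_marg <- array(NA_real_, c(grid_n, grid_n, grid_n))
  cache <- vector("list", grid_n * grid_n * grid_n)
  idx3 <- 0L
  for (im in seq_len(grid_n)) {
    beta_rows <- (im - 1L) * k + seq_len(k)
    for (iw in seq_len(grid_n)) {
      rows <- c(beta_rows, grid_n * k + iw)
      omg <- omega_rows[rows]
      for (ip in seq_len(grid_n)) {
        idx3 <- idx3 + 1L
        props <- c(rep(p0_grid[ip] / k, k), 1 - p0_grid[ip])
        site_ll <- mixture_loglik(ll[rows, , drop = FALSE], props)
        log_marg[ip, im, iw] <- sum(site_ll)
        cache[[idx3]] <- list(rows = rows, props = props, omg = omg)
      }
    }
  }
  lm <- as.numeric(aperm(log_marg, c(1, 2, 3)))
  # careful: fill order above is ip fastest within (im, iw); rebuild weights
  lmv <- numeric(idx3)
  idx3 <- 0L
  for (im in seq_len(grid_n)) for (iw in seq_len(grid_n))
    for (ip in seq_len(grid_n)) {
      idx3 <- idx3 + 1L
      lmv[idx3] <- log_marg[ip, im, iw]
    }
  wts <- exp(lmv - max(lmv))
  wts <- wts / sum(wts)
  omega_bar <- numeric(n_site)
  pp_pos <- numeric(n_site)
  for (g in seq_along(cache)) {
    if (wts[g] < 1e-12) next
    ci <- cache[[g]]
    post <- class_posterior(ll[ci$rows, , drop = FALSE], ci$props)
    omega_bar <- omega_bar + wts[g] * as.numeric(crossprod(post, ci$omg))
    pp_pos <- pp_pos + wts[g] *
      as.numeric(colSums(post[ci$omg > 1, , drop = FALSE]))
  }
  out <- data.frame(site = seq_len(n_site), omega_bar = omega_bar,
                    pp_positive = pp_pos)
  class(out) <- c("site_posterior", "data.frame")
  out
}

#' Conservation index of a site
#'
#' `CI = 1 - omega_bar` for sites with mean dN/dS below 1; neutral and
#' positively selected sites (`omega_bar >= 1`) get CI = 0 exactly, so
#' the index runs from 0 (unconstrained) to 1 (fully constrained).
#'
#' @param omega_bar Posterior mean dN/dS per site (vector), or a
#'   `site_posterior` data frame.
#' @return Numeric vector of CI values in `[0, 1]`.
#' @export
conservation_index <- function(omega_bar) {
  if (inherits(omega_bar, "site_posterior") || is.data.frame(omega_bar))
    omega_bar <- omega_bar$omega_bar
  if (any(omega_bar < 0)) stop("omega_bar must be >= 0")
  ifelse(omega_bar >= 1, 0, 1 - omega_bar)
}

#' Flag positively selected sites
#'
#' @param posteriors A `site_posterior` data frame.
#' @param threshold Posterior-probability cutoff (default 0.95).
#' @return Subset of `posteriors` with `pp_positive > threshold`,
#'   ordered by site.
#' @export
flag_positive_sites <- function(posteriors, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  out <- posteriors[posteriors$pp_positive > threshold,
                    c("site", "omega_bar", "pp_positive")]
  rownames(out) <- NULL
  out
}

#' Classify alignment columns by conservation
#'
#' Works on the amino-acid view of an alignment restricted to functional
#' sequences. A column is `unchanged` if a single residue state occurs
#' among non-missing entries, `conservative` if all states fall within
#' one chemical property group (see [aa_property_groups()]),
#' `variable` otherwise, and `undetermined` when entirely missing.
#' `tolerance` allows up to that many deviant sequences to be ignored
#' when testing the unchanged/conservative criteria (default 0, strict).
#'
#' @param aa Character matrix from [as_aa_matrix()] (or a
#'   [codon_alignment()], converted internally).
#' @param groups Property partition (default [aa_property_groups()]).
#' @param tolerance Number of deviant sequences tolerated per column.
#' @return Factor vector over columns with levels
#'   `unchanged < conservative < variable < undetermined`.
#' @export
classify_columns <- function(aa, groups = aa_property_groups(), tolerance = 0) {
  if (inherits(aa, "codon_alignment")) aa <- as_aa_matrix(aa)
  group_of <- rep(names(groups), lengths(groups))
  names(group_of) <- unlist(groups)
  cls <- apply(aa, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return("undetermined")
    tab <- sort(table(col), decreasing = TRUE)
    if (sum(tab) - tab[1] <= tolerance) return("unchanged")
    gtab <- sort(table(group_of[col]), decreasing = TRUE)
    if (sum(gtab) - gtab[1] <= tolerance) return("conservative")
    "variable"
  })
  factor(cls, levels = c("unchanged", "conservative", "variable",
                         "undetermined"))
}

#' Residue composition of a protein sequence
#'
#' Reports per-residue percentages for the full sequence and an optional
#' region of interest (for example a proline-rich domain), together with
#' the combined proline + glutamine percentage, the hallmark of P/Q-rich
#' enamel matrix proteins.
#'
#' @param seq Amino-acid string (one-letter code).
#' @param region Optional `c(start, end)` 1-based inclusive residue span.
#' @return List with `full` and (if requested) `region` percentage
#'   tables, plus `pq_percent` entries for each.
#' @export
residue_composition <- function(seq, region = NULL) {
  chars <- strsplit(toupper(seq), "")[[1]]
  aas <- sort(unique(unlist(aa_property_groups())))
  comp <- function(x) {
    tab <- table(factor(x, levels = aas))
    100 * as.numeric(tab) / length(x) -> pct
    names(pct) <- aas
    pct
  }
  out <- list(full = comp(chars),
              pq_percent = list(full = NULL))
  out$pq_percent$full <- unname(out$full["P"] + out$full["Q"])
  if (!is.null(region)) {
    if (region[1] < 1 || region[2] > length(chars) || region[1] > region[2])
      stop("region outside sequence (length ", length(chars), ")")
    rc <- comp(chars[region[1]:region[2]])
    out$region <- rc
    out$pq_percent$region <- unname(rc["P"] + rc["Q"])
  }
  out
}

#' Candidate mutation-sensitive sites
#'
#' Ranks conserved alignment positions as candidates for
#' disease-associated substitution: sites classified `unchanged` or
#' `conservative` are retained and ordered by conservation index
#' (descending, ties broken by site index), the logic being that a
#' substitution at a position held constant across ~200 My of evolution
#' is most likely to disrupt function.
#'
#' @param profile Data frame with columns `site`, `ci`, `class` (as built
#'   by [conservation_profile()]).
#' @return Data frame of candidate sites with `site`, `class`, `ci`,
#'   ranked.
#' @export
candidate_disease_sites <- function(profile) {
  keep <- profile$class %in% c("unchanged", "conservative")
  out <- profile[keep, c("site", "class", "ci")]
  out <- out[order(-out$ci, out$site), ]
  rownames(out) <- NULL
  out
}

#' Per-site conservation profile
#'
#' Combines empirical-Bayes posteriors, the conservation index, column
#' conservation classes and positive-selection flags into the per-site
#' table used for candidate-site prediction and plotting.
#'
#' @param fit A site-class `codon_fit` (typically M8).
#' @param aln Alignment used for column classification; defaults to the
#'   fit's alignment. Pass a functional-sequences-only alignment if
#'   pseudogenes were fitted.
#' @param method Posterior method, see [site_posteriors()].
#' @param pp_threshold Positive-site flag cutoff (default 0.95).
#' @param groups Property groups for [classify_columns()].
#' @return Data frame of class `conservation_profile`: `site`,
#'   `omega_bar`, `pp_positive`, `ci`, `class`, `positive_site`,
#'   `candidate_disease_site`.
#' @export
conservation_profile <- function(fit, aln = fit$aln,
                                 method = c("NEB", "BEB"),
                                 pp_threshold = 0.95,
                                 groups = aa_property_groups()) {
  method <- match.arg(method)
  post <- site_posteriors(fit, method = method)
  ci <- conservation_index(post)
  cls <- classify_columns(aln, groups = groups)
  out <- data.frame(site = post$site,
                    omega_bar = post$omega_bar,
                    pp_positive = post$pp_positive,
                    ci = ci,
                    class = cls,
                    positive_site = post$pp_positive > pp_threshold)
  out$candidate_disease_site <- !out$positive_site &
    out$class %in% c("unchanged", "conservative")
  class(out) <- c("conservation_profile", "data.frame")
  out
}
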