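# Maximum-likelihood fitting of codon models and likelihood-ratio tests.
#
# Optimization is box-constrained quasi-Newton (L-BFGS-B) on transformed
# parameters: positive parameters on the log scale, proportions on the
# logit scale, the M8 selection-class omega as 1 + exp(z). Branch lengths
# are by default the input tree's values times one optimized global scale
# factor; full per-branch optimization is available behind a flag.

.par_bounds <- list(
  log_kappa   = c(log(0.02), log(100)),
  log_omega   = c(log(1e-6), log(50)),
  log_p       = c(log(0.005), log(100)),
  log_q       = c(log(0.005), log(100)),
  logit_p0    = c(-12, 12),
  z_omega_s   = c(-15, log(49)),
  log_scale   = c(-6, 6),
  log_blen    = c(log(1e-7), log(20))
)

pack_start <- function(kind, n_ratio, optimize_scale, init = NULL) {
  d <- list(log_kappa = log(2))
  if (kind == "M0" && n_ratio <= 1) d$log_omega <- log(0.4)
  if (kind == "branch") for (r in seq_len(n_ratio))
    d[[paste0("log_omega", r)]] <- log(0.4)
  if (kind %in% c("M7", "M8")) { d$log_p <- log(1); d$log_q <- log(1) }
  if (kind == "M8") { d$logit_p0 <- stats::qlogis(0.9); d$z_omega_s <- log(1) }
  if (optimize_scale) d$log_scale <- 0
  if (!is.null(init)) for (nm in names(init)) d[[nm]] <- init[[nm]]
  unlist(d)
}

bounds_for <- function(par_names) {
  key <- ifelse(grepl("^log_omega[0-9]*$", par_names), "log_omega",
         ifelse(grepl("^log_blen[0-9]+$", par_names), "log_blen", par_names))
  lo <- vapply(key, function(k) .par_bounds[[k]][1], numeric(1))
  hi <- vapply(key, function(k) .par_bounds[[k]][2], numeric(1))
  list(lower = lo, upper = hi)
}

unpack_params <- function(theta, kind, k, n_ratio) {
  g <- function(nm) unname(theta[nm])
  out <- list(kappa = exp(g("log_kappa")),
              scale = if ("log_scale" %in% names(theta)) exp(g("log_scale")) else 1)
  if (kind == "M0" && n_ratio <= 1) {
    out$model <- site_class_model("M0", omega = exp(g("log_omega")))
  } else if (kind == "branch") {
    out$branch_omegas <- exp(theta[grep("^log_omega[0-9]+$", names(theta))])
    out$model <- site_class_model("M0", omega = out$branch_omegas[1])
  } else if (kind == "M7") {
    out$model <- site_class_model("M7", p = exp(g("log_p")), q = exp(g("log_q")), k = k)
  } else {
    out$model <- site_class_model("M8", p = exp(g("log_p")), q = exp(g("log_q")),
                                  p0 = stats::plogis(g("logit_p0")),
                                  omega_s = 1 + exp(g("z_omega_s")), k = k)
  }
  out
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits M0, M7 or M8 site-class models, or a multi-ratio branch model
#' (one dN/dS per branch class defined by `branch_spec`, the site model
#' then being single-class). Transition/transversion ratio, the model's
#' dN/dS parameters and a global branch-length scale factor are
#' optimized jointly; random restarts guard against local optima.
#'
#' @param aln A [codon_alignment()].
#' @param tree [ape::phylo] tree with branch lengths (expected
#'   substitutions per codon); tips must match `aln$taxa`.
#' @param model `"M0"`, `"M7"` or `"M8"`.
#' @param branch_spec Optional [branch_classes()]; implies a multi-ratio
#'   M0-style model with one dN/dS per class.
#' @param k Discrete beta categories for M7/M8 (default 10).
#' @param freq Frequency estimator, `"F3x4"` (default) or `"F61"`.
#' @param pi Optional codon frequency vector overriding `freq`.
#' @param optimize_scale Optimize a global branch-length multiplier
#'   (default `TRUE`).
#' @param optimize_branch_lengths Optimize every branch length
#'   individually (slow; default `FALSE`).
#' @param n_restarts Number of additional random restarts (default 2).
#' @param control Passed to [stats::optim()] (`factr`, `maxit`).
#' @return Object of class `codon_fit`: maximized `lnL`, MLEs, per-class
#'   dN/dS, convergence diagnostics, and cached per-site class
#'   log-likelihoods for downstream empirical-Bayes steps.
#' @export
fit_codon_model <- function(aln, tree, model = c("M0", "M7", "M8"),
                            branch_spec = NULL, k = 10,
                            freq = c("F3x4", "F61"), pi = NULL,
                            optimize_scale = TRUE,
                            optimize_branch_lengths = FALSE,
                            n_restarts = 2, control = list()) {
  model <- match.arg(model)
  freq <- match.arg(freq)
  stopifnot(inherits(aln, "codon_alignment"), inherits(tree, "phylo"))
  if (length(aln$taxa) < 3) stop("need at least 3 taxa")
  if (aln$length_codons < 1) stop("empty alignment")
  if (!setequal(tree$tip.label, aln$taxa))
    stop("tree tip labels and alignment taxa differ")
  if (!is.null(branch_spec)) {
    if (model != "M0")
      stop("branch models combine only with the single-class site model")
    if (length(branch_spec) != nrow(tree$edge))
      stop("branch_spec length does not match tree edges")
    n_ratio <- if (!is.null(attr(branch_spec, "labels")))
      length(attr(branch_spec, "labels")) else max(branch_spec) + 1L
    tab <- tabulate(as.integer(branch_spec) + 1L, n_ratio)
    if (any(tab == 0)) stop("branch ratio class with zero member branches")
    kind <- "branch"
  } else {
    n_ratio <- 1L
    kind <- model
  }
  if (is.null(pi)) pi <- codon_frequencies(aln, method = freq)

  states <- codon_state_matrix(aln, taxa = tree$tip.label)
  degenerate <- all(apply(states, 2L, function(col)
    length(unique(col[!is.na(col)])) <= 1L))
  if (degenerate)
    warning("alignment has no variable columns; dN/dS is unidentifiable ",
            "and branch lengths shrink to zero")

  tr <- tree
  blen_mode <- isTRUE(optimize_branch_lengths)
  theta0 <- pack_start(kind, n_ratio, optimize_scale && !blen_mode)
  if (blen_mode) {
    bl0 <- pmax(tree$edge.length, 1e-6)
    theta0 <- c(theta0[!grepl("^log_scale$", names(theta0))],
                stats::setNames(log(bl0), paste0("log_blen", seq_along(bl0))))
  }
  bnds <- bounds_for(names(theta0))

  negll <- function(theta) {
    pp <- unpack_params(theta, kind, k, n_ratio)
    trx <- tr
    if (blen_mode)
      trx$edge.length <- exp(unname(theta[grep("^log_blen", names(theta))]))
    res <- try({
      if (kind == "branch") {
        ll <- class_site_loglik(states, trx, NULL, pp$kappa, pi, pp$scale,
                                branch_omegas = pp$branch_omegas,
                                branch_cls = as.integer(branch_spec))
        sum(ll[1, ])
      } else {
        ll <- class_site_loglik(states, trx, pp$model$omegas, pp$kappa, pi,
                                pp$scale)
        sum(mixture_loglik(ll, pp$model$props))
      }
    }, silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res)) return(1e10)
    -res
  }

  ctrl <- utils::modifyList(list(factr = 1e8, maxit = 500), control)
  run_opt <- function(start) {
    stats::optim(start, negll, method = "L-BFGS-B",
                 lower = bnds$lower, upper = bnds$upper, control = ctrl)
  }
  best <- run_opt(theta0)
  tried <- 1L
  if (n_restarts > 0) {
    for (r in seq_len(n_restarts)) {
      jitter <- stats::runif(length(theta0), -1, 1)
      start <- pmin(pmax(theta0 + jitter, bnds$lower), bnds$upper)
      cand <- try(run_opt(start), silent = TRUE)
      tried <- tried + 1L
      if (!inherits(cand, "try-error") && cand$value < best$value) best <- cand
    }
  }
  theta_hat <- best$par
  pp <- unpack_params(theta_hat, kind, k, n_ratio)
  if (blen_mode)
    tr$edge.length <- exp(unname(theta_hat[grep("^log_blen", names(theta_hat))]))

  # cache class-site log-likelihoods at the MLE for empirical Bayes
  if (kind == "branch") {
    cls_ll <- class_site_loglik(states, tr, NULL, pp$kappa, pi, pp$scale,
                                branch_omegas = pp$branch_omegas,
                                branch_cls = as.integer(branch_spec))
    site_ll <- cls_ll[1, ]
  } else {
    cls_ll <- class_site_loglik(states, tr, pp$model$omegas, pp$kappa, pi,
                                pp$scale)
    site_ll <- mixture_loglik(cls_ll, pp$model$props)
  }

  at_bound <- names(theta_hat)[theta_hat <= bnds$lower + 1e-3 |
                               theta_hat >= bnds$upper - 1e-3]
  converged <- best$convergence == 0
  if (!converged)
    warning("optimizer did not report convergence (code ", best$convergence,
            "); result returned with warning flag")

  structure(list(
    kind = if (kind == "branch") "branch" else model,
    lnL = -best$value,
    model = pp$model,
    kappa = pp$kappa,
    scale = pp$scale,
    branch_omegas = pp$branch_omegas,
    branch_spec = branch_spec,
    pi = pi,
    k = k,
    freq = attr(pi, "method"),
    n_free_params = length(theta_hat),
    convergence = converged,
    degenerate = degenerate,
    at_bound = at_bound,
    n_starts = tried,
    site_loglik = site_ll,
    class_loglik = cls_ll,
    tree = tr,
    aln = aln
  ), class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon_fit", x$kind, " lnL =", sprintf("%.4f", x$lnL),
      " np =", x$n_free_params, "\n")
  cat("kappa =", signif(x$kappa, 4), " scale =", signif(x$scale, 4), "\n")
  if (x$kind == "branch") {
    cat("branch omegas:", paste(signif(x$branch_omegas, 3), collapse = ", "), "\n")
  } else {
    cat("params:", paste(names(x$model$params),
                         signif(unlist(x$model$params), 4),
                         sep = "=", collapse = ", "), "\n")
  }
  if (!x$convergence) cat("WARNING: not converged\n")
  if (length(x$at_bound)) cat("at bound:", paste(x$at_bound, collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested codon-model fits
#'
#' The statistic is `2 * (lnL_alt - lnL_null)`, clamped at zero, compared
#' to an upper-tail chi-square with df equal to the difference in free
#' parameter counts (M7 vs M8: 2; one-ratio vs two-ratio: 1). The plain
#' chi-square reference is used throughout; no boundary-mixture
#' correction is applied.
#'
#' @param null,alt `codon_fit` objects, `null` nested in `alt`.
#' @return Object of class `lrt_result` with `statistic`, `df`,
#'   `p_value`.
#' @export
lrt <- function(null, alt) {
  stopifnot(inherits(null, "codon_fit"), inherits(alt, "codon_fit"))
  df <- alt$n_free_params - null$n_free_params
  if (df <= 0) stop("alternative must have more free parameters than null")
  stat <- 2 * (alt$lnL - null$lnL)
  if (stat < 0) {
    if (stat < -1e-4 * max(1, abs(null$lnL)) - 0.05)
      warning("alternative lnL below null beyond tolerance (",
              signif(stat / 2, 4), "); statistic clamped to 0")
    stat <- 0
  }
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 null = null$kind, alt = alt$kind,
                 lnL_null = null$lnL, lnL_alt = alt$lnL),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2dlnL = %.4f (df %d), p = %.3g\n",
              x$null, x$alt, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-class dN/dS report for a branch-model fit
#'
#' @param fit A `codon_fit` from a multi-ratio branch model.
#' @return Data frame with one row per ratio class: label, dN/dS
#'   estimate, number of member branches, and a `positive_selection`
#'   flag for classes with dN/dS > 1.
#' @export
branch_dnds_report <- function(fit) {
  stopifnot(inherits(fit, "codon_fit"))
  if (is.null(fit$branch_spec)) {
    return(data.frame(class = "background",
                      omega = fit$model$params$omega,
                      n_branches = nrow(fit$tree$edge),
                      positive_selection = fit$model$params$omega > 1))
  }
  labs <- attr(fit$branch_spec, "labels")
  cls <- as.integer(fit$branch_spec)
  data.frame(class = labs,
             omega = unname(fit$branch_omegas),
             n_branches = tabulate(cls + 1L, length(labs)),
             positive_selection = unname(fit$branch_omegas) > 1)
}
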