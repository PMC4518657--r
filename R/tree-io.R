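# Tree I/O and branch-class utilities. Trees are ape "phylo" objects
# throughout; this file only adds the validation and determinism layers
# the analysis needs.

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with the package's validation rules: leaf
#' labels must be unique, branch lengths non-negative, and polytomies are
#' resolved deterministically (left-to-right insertion of zero-length
#' branches via [ape::multi2di()] with `random = FALSE`) so that
#' downstream likelihoods are reproducible.
#'
#' @param path Newick file.
#' @param resolve_polytomies Resolve multifurcations (default `TRUE`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path, resolve_polytomies = TRUE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_tree(tr)
  if (resolve_polytomies && !ape::is.binary(tr))
    tr <- ape::multi2di(tr, random = FALSE)
  tr
}

#' Write a Newick tree
#'
#' Branch lengths are written with enough digits that
#' `read_newick(write_newick(t))` preserves them to 10 significant
#' figures.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in tree")
  invisible(tree)
}

#' Assign branches to dN/dS ratio classes
#'
#' Builds the edge-to-class map used by multi-ratio branch models. Class 0
#' is the background; each element of `foreground` is a named set of tip
#' labels defining a clade whose branches (stem branch plus all branches
#' within the clade) get their own ratio class, numbered in list order. A
#' single tip label marks just its terminal branch.
#'
#' @param tree An [ape::phylo] tree.
#' @param foreground Named list of character vectors of tip labels.
#' @return Object of class `branch_classes`: integer vector over edges
#'   (in `tree$edge` order) with attribute `labels` naming classes
#'   `c("background", names(foreground))`.
#' @export
branch_classes <- function(tree, foreground) {
  stopifnot(inherits(tree, "phylo"))
  if (length(foreground) == 0) stop("empty foreground list")
  if (is.null(names(foreground)) || any(!nzchar(names(foreground))))
    stop("foreground clades must be named")
  cls <- integer(nrow(tree$edge))
  ntip <- length(tree$tip.label)
  for (i in seq_along(foreground)) {
    tips <- foreground[[i]]
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss)) stop("foreground tips not in tree: ",
                           paste(miss, collapse = ", "))
    tip_idx <- match(tips, tree$tip.label)
    if (length(tip_idx) == 1L) {
      edges <- which(tree$edge[, 2] == tip_idx)
    } else {
      mrca <- ape::getMRCA(tree, tip_idx)
      desc <- clade_descendants(tree, mrca)
      if (!setequal(intersect(desc, seq_len(ntip)), tip_idx))
        stop("foreground clade '", names(foreground)[i],
             "' is not monophyletic in the tree")
      edges <- which(tree$edge[, 2] %in% c(mrca, desc))
    }
    if (any(cls[edges] != 0L))
      stop("foreground clades overlap at class '", names(foreground)[i], "'")
    cls[edges] <- i
  }
  structure(cls, labels = c("background", names(foreground)),
            class = "branch_classes")
}

# all node+tip indices below a node (excluding the node itself)
clade_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ntip])
  }
  out
}
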