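#' Cophenetic (patristic) distances between tips
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric matrix with zero diagonal, dimnames = tip labels.
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have complete branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Exclude long-branch outlier tips
#'
#' For every tip, the mean cophenetic distance to all other tips is computed;
#' tips whose mean exceeds the grand mean of tip means plus `k` standard
#' deviations are excluded.  A single pass (no iteration), used to guard the
#' downstream rooting and ancestral reconstruction against proteins evolving
#' much faster than the rest of the tree.
#'
#' @param tree An `ape::phylo` tree with branch lengths and >= 4 tips.
#' @param k Number of standard deviations above the mean (default 3).
#' @return List with `keep` and `excluded` (tip label vectors), `tip_means`,
#'   `threshold`, and `tree` pruned to the retained tips.
#' @export
filter_outliers <- function(tree, k = 3.0) {
  if (ape::Ntip(tree) < 4) stop("outlier filtering requires >= 4 tips")
  d <- cophenetic_distances(tree)
  n <- nrow(d)
  tip_means <- rowSums(d) / (n - 1)
  thr <- mean(tip_means) + k * stats::sd(tip_means)
  keep <- names(tip_means)[tip_means <= thr | !is.finite(thr)]
  excluded <- setdiff(rownames(d), keep)
  pruned <- if (length(excluded)) ape::drop.tip(tree, excluded) else tree
  list(keep = keep, excluded = excluded, tip_means = tip_means,
       threshold = thr, tree = pruned)
}

#' Resolve multifurcations deterministically
#'
#' Polytomies are expanded left-to-right into binary nodes joined by
#' zero-length branches (deterministic; no randomisation), as required by
#' the ancestral-state machinery.
#'
#' @param tree An `ape::phylo` tree.
#' @return A binary `ape::phylo` tree.
#' @export
resolve_multifurcations <- function(tree) {
  if (ape::is.binary.phylo(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}

#' Read / write Newick trees
#'
#' Thin wrappers over the `ape` Newick parser that validate branch lengths,
#' so every tree entering the pipeline carries usable edge lengths.
#'
#' @param path File path.
#' @param tree An `ape::phylo` tree.
#' @return `read_newick` returns a `phylo` (or `multiPhylo`) object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  check1 <- function(t) {
    if (is.null(t$edge.length)) stop("tree in ", path, " lacks branch lengths")
    t
  }
  if (inherits(tr, "multiPhylo")) {
    for (t in tr) check1(t)
    tr
  } else check1(tr)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
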