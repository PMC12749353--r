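# Minimal-ancestor-deviation rooting.
#
# For a candidate root position rho on a branch, every tip pair (b, c) whose
# path crosses rho would, under a strict molecular clock, satisfy
# d(rho, b) = d(rho, c) = d(b, c) / 2.  The relative deviation of a pair is
# r = |2 d(rho, b) / d(b, c) - 1|, and the score of a position is the
# root-mean-square of r over all straddling pairs.  The root is the global
# minimiser over all branches; within a branch the squared score is a
# quadratic in the offset, so the per-branch minimiser is closed-form.

# Adjacency list of an unrooted tree: for node i, neighbours and edge info.
tree_adjacency <- function(tree) {
  m <- nrow(tree$edge)
  adj <- vector("list", ape::Ntip(tree) + tree$Nnode)
  for (e in seq_len(m)) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; len <- tree$edge.length[e]
    adj[[u]] <- rbind(adj[[u]], c(v, len, e))
    adj[[v]] <- rbind(adj[[v]], c(u, len, e))
  }
  adj
}

# Newick string for the subtree reached from `node` arriving from `from`.
subtree_newick <- function(node, from, adj, tip_labels, n_tip) {
  nb <- adj[[node]]
  out <- character(0)
  for (i in seq_len(nrow(nb))) {
    child <- nb[i, 1]; len <- nb[i, 2]
    if (child == from) next
    out <- c(out, paste0(subtree_newick(child, node, adj, tip_labels, n_tip),
                         ":", format(len, digits = 15)))
  }
  if (length(out) == 0) return(tip_labels[node])
  paste0("(", paste(out, collapse = ","), ")")
}

#' Root a tree by minimal ancestor deviation
#'
#' Places the root at the branch position minimising the RMS relative
#' deviation from the midpoint expectation over all tip pairs that straddle
#' the candidate position (see the package vignette for the criterion).
#' The per-branch minimiser is found analytically (the squared score is
#' quadratic in the offset) and clamped to the branch; ties between branches
#' are broken by the smaller branch index, then the smaller offset.
#'
#' @param tree An `ape::phylo` tree (rooted input is unrooted first);
#'   >= 2 tips, branch lengths >= 0, not all zero.
#' @return List: `tree` (rooted binary `phylo`), `edge` (index of the root
#'   branch in the unrooted tree's edge matrix), `offset` (distance of the
#'   root from the edge's first node), `score` (the minimal RMS deviation),
#'   and `unrooted` (the unrooted input).
#' @export
mad_root <- function(tree) {
  if (ape::Ntip(tree) < 2) stop("need >= 2 tips to root")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (all(tree$edge.length <= 0)) stop("all branch lengths are zero")
  if (ape::Ntip(tree) == 2) {
    tot <- sum(tree$edge.length)
    lab <- sort(tree$tip.label)
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", lab[1], tot / 2, lab[2], tot / 2)
    return(list(tree = ape::read.tree(text = nwk), edge = 1L,
                offset = tot / 2, score = 0, unrooted = tree))
  }
  tu <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n_tip <- ape::Ntip(tu)
  D <- ape::dist.nodes(tu)
  m <- nrow(tu$edge)
  best <- list(score = Inf, edge = NA_integer_, offset = NA_real_)
  for (e in seq_len(m)) {
    u <- tu$edge[e, 1]; v <- tu$edge[e, 2]; len <- tu$edge.length[e]
    on_v_side <- abs(D[seq_len(n_tip), u] - (D[seq_len(n_tip), v] + len)) < 1e-9
    tips_v <- which(on_v_side)
    tips_u <- setdiff(seq_len(n_tip), tips_v)
    if (length(tips_u) == 0 || length(tips_v) == 0) next
    a <- rep(D[tips_u, u], times = length(tips_v))              # d(b, u)
    cv <- rep(D[tips_v, v], each = length(tips_u))              # d(c, v)
    dbc <- a + len + cv
    ok <- dbc > 0
    if (!any(ok)) next
    alpha <- 2 / dbc[ok]
    beta <- 2 * a[ok] / dbc[ok] - 1
    x <- -sum(alpha * beta) / sum(alpha^2)
    x <- min(max(x, 0), len)
    sc <- sqrt(mean((alpha * x + beta)^2))
    if (sc < best$score - 1e-12 ||
        (abs(sc - best$score) <= 1e-12 &&
         (e < best$edge || (e == best$edge && x < best$offset)))) {
      best <- list(score = sc, edge = e, offset = x)
    }
  }
  if (!is.finite(best$score)) stop("MAD criterion undefined on this tree")
  rooted <- root_at_position(tu, best$edge, best$offset)
  list(tree = rooted, edge = best$edge, offset = best$offset,
       score = best$score, unrooted = tu)
}

#' Root an unrooted tree at a position along a branch
#'
#' Inserts a root node on branch `edge` at distance `offset` from the
#' branch's first node (`tree$edge[edge, 1]`) and reorients all branches.
#'
#' @param tree Unrooted `ape::phylo` tree.
#' @param edge Row index into `tree$edge`.
#' @param offset Distance from `tree$edge[edge, 1]`, in `[0, length]`.
#' @return A rooted binary `ape::phylo` tree.
#' @export
root_at_position <- function(tree, edge, offset) {
  len <- tree$edge.length[edge]
  if (offset < -1e-12 || offset > len + 1e-12)
    stop("offset outside the branch")
  offset <- min(max(offset, 0), len)
  u <- tree$edge[edge, 1]; v <- tree$edge[edge, 2]
  adj <- tree_adjacency(tree)
  labels <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  left <- paste0(subtree_newick(u, v, adj, labels, ape::Ntip(tree)),
                 ":", format(offset, digits = 15))
  right <- paste0(subtree_newick(v, u, adj, labels, ape::Ntip(tree)),
                  ":", format(len - offset, digits = 15))
  out <- ape::read.tree(text = paste0("(", left, ",", right, ");"))
  resolve_multifurcations(out)
}
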