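#' Rate of quaternary-structure change along a tree
#'
#' Iterates over every parent-child node pair of the tree (tip edges
#' included).  A pair where either endpoint is unresolved (highest marginal
#' probability not above 0.51 in ML mode) is skipped from both numerator and
#' denominator.  A counted pair "changes" when the two endpoint states
#' differ; a change is a gain when the child has more subunits than the
#' parent, a loss when fewer, and lateral when the subunit counts are equal
#' but the topology class differs.  Rates are the counts divided by the
#' number of pairs used.
#'
#' In ML mode the node state is the argmax of the marginal probabilities;
#' ties are broken toward the parent's state (processed root-to-tip), which
#' avoids counting spurious changes on exactly ambiguous nodes.
#'
#' @param asr A `qs_asr` object from [fit_er_asr()] or [acctran_asr()].
#' @param state_subunits Named numeric vector mapping each state label to
#'   its subunit count.
#' @return List of class `qs_change_rate`: `n_pairs_total`, `n_pairs_used`,
#'   `n_changes`, `n_gains`, `n_losses`, `n_lateral`, `rate_total`,
#'   `rate_gain`, `rate_loss`.
#' @export
qs_change_rate <- function(asr, state_subunits) {
  tree <- asr$tree
  miss <- setdiff(asr$states, names(state_subunits))
  if (length(miss))
    stop("subunit counts missing for state(s): ", paste(miss, collapse = ", "))
  n_node <- ape::Ntip(tree) + tree$Nnode
  if (nrow(asr$prob) != n_node) stop("tree / estimate mismatch")
  # assign node states preorder so ties defer to the parent
  state_idx <- integer(n_node)
  pe <- ape::reorder.phylo(tree, "postorder")$edge
  root <- ape::Ntip(tree) + 1L
  pick <- function(node, parent_state) {
    p <- asr$prob[node, ]
    mx <- max(p)
    cand <- which(p >= mx - 1e-12)
    if (!is.na(parent_state) && parent_state %in% cand) parent_state
    else cand[1]
  }
  state_idx[root] <- pick(root, NA_integer_)
  for (i in rev(seq_len(nrow(pe))))
    state_idx[pe[i, 2]] <- pick(pe[i, 2], state_idx[pe[i, 1]])
  resolved <- asr$resolved
  n_total <- nrow(tree$edge)
  used <- resolved[tree$edge[, 1]] & resolved[tree$edge[, 2]]
  sp <- state_idx[tree$edge[, 1]]
  sc <- state_idx[tree$edge[, 2]]
  su <- state_subunits[asr$states]
  changed <- used & (sp != sc)
  gains <- changed & (su[sc] > su[sp])
  losses <- changed & (su[sc] < su[sp])
  lateral <- changed & (su[sc] == su[sp])
  n_used <- sum(used)
  rate <- function(x) if (n_used > 0) sum(x) / n_used else NA_real_
  structure(list(n_pairs_total = n_total, n_pairs_used = n_used,
                 n_changes = sum(changed), n_gains = sum(gains),
                 n_losses = sum(losses), n_lateral = sum(lateral),
                 rate_total = rate(changed), rate_gain = rate(gains),
                 rate_loss = rate(losses)),
            class = "qs_change_rate")
}

#' Classify the root of a reconstructed tree
#'
#' The root is a homomer or monomer root when its most probable state has
#' marginal probability strictly above `threshold` (default 0.51) and that
#' state's subunit count is above / equal to one; otherwise it is
#' unresolved and the tree is excluded from root-type strata.
#'
#' @inheritParams qs_change_rate
#' @param threshold Resolution probability (strict `>`, default 0.51).
#' @return `"homomer"`, `"monomer"` or `"unresolved"`.
#' @export
root_type <- function(asr, state_subunits, threshold = 0.51) {
  root <- ape::Ntip(asr$tree) + 1L
  p <- asr$prob[root, ]
  if (max(p) <= threshold) return("unresolved")
  st <- asr$states[which.max(p)]
  if (state_subunits[st] > 1) "homomer" else "monomer"
}
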