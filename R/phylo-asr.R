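# Equal-rates Mk likelihood and marginal ancestral reconstruction.
#
# Under the ER model with k states and rate r, all off-diagonal entries of
# the generator equal r, so the transition probabilities have the closed
# form P_ij(t) = (1 - exp(-k r t)) / k for i != j and
# P_ii(t) = 1/k + (k - 1)/k * exp(-k r t).  Likelihoods are computed by the
# pruning algorithm with per-edge rescaling; marginal node probabilities by
# a pre-order "outside" pass, equivalent to re-rooting at every node.

er_pmat <- function(rate, t, k) {
  e <- exp(-k * rate * t)
  off <- (1 - e) / k
  p <- matrix(off, k, k)
  diag(p) <- off + e
  p
}

# Precomputed traversal structure reused across likelihood evaluations.
asr_prep <- function(tree, tip_states, states) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary.phylo(tree)) tree <- resolve_multifurcations(tree)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  if (is.null(names(tip_states)) || !all(tree$tip.label %in% names(tip_states)))
    stop("tip_states must be a named vector covering all tip labels")
  tip_states <- tip_states[tree$tip.label]
  if (anyNA(tip_states)) stop("missing tip state")
  if (is.null(states)) states <- sort(unique(as.character(tip_states)))
  if (!all(tip_states %in% states)) stop("tip state outside the state set")
  el <- tree$edge.length
  if (is.null(el)) stop("tree must have branch lengths")
  el <- pmax(el, 1e-8)  # zero-length floor for the transition probabilities
  po <- ape::reorder.phylo(tree, "postorder")
  k <- length(states)
  tipL <- matrix(0, n_tip, k)
  tipL[cbind(seq_len(n_tip), match(tip_states, states))] <- 1
  ekey <- paste(tree$edge[, 1], tree$edge[, 2])
  post2orig <- match(paste(po$edge[, 1], po$edge[, 2]), ekey)
  list(tree = tree, states = states, k = k, n_tip = n_tip, n_node = n_node,
       post_edge = po$edge, post_len = pmax(po$edge.length, 1e-8),
       post2orig = post2orig,
       edge = tree$edge, edge_len = el, tipL = tipL,
       tip_states = tip_states)
}

# Pruning pass: conditional ("inside") likelihoods and the log-likelihood.
er_inside <- function(prep, rate, root_prior, store_down = TRUE) {
  k <- prep$k
  L <- matrix(1, prep$n_node, k)
  L[seq_len(prep$n_tip), ] <- prep$tipL
  # per-edge rescaled P(t_e) %*% L[child], kept only for the marginal pass
  down <- if (store_down) matrix(NA_real_, nrow(prep$edge), k)
  logscale <- 0
  pe <- prep$post_edge
  # ER transition matrix is off*J + e*I, so P %*% x = off*sum(x) + e*x
  ev <- exp(-k * rate * prep$post_len)
  off <- (1 - ev) / k
  for (i in seq_len(nrow(pe))) {
    par <- pe[i, 1]; ch <- pe[i, 2]
    lc <- L[ch, ]
    dc <- off[i] * sum(lc) + ev[i] * lc
    s <- sum(dc)
    if (s <= 0 || !is.finite(s)) stop("non-finite likelihood contribution")
    dc <- dc / s
    logscale <- logscale + log(s)
    L[par, ] <- L[par, ] * dc
    if (store_down) down[prep$post2orig[i], ] <- dc
  }
  root <- prep$n_tip + 1L
  lik <- sum(root_prior * L[root, ])
  if (lik <= 0 || !is.finite(lik)) stop("non-finite likelihood")
  list(L = L, down = down, loglik = log(lik) + logscale)
}

er_loglik <- function(prep, rate, root_prior) {
  er_inside(prep, rate, root_prior, store_down = FALSE)$loglik
}

#' Equal-rates Mk ancestral state reconstruction by maximum likelihood
#'
#' Fits the single transition rate of the equal-rates (ER) Mk model by
#' maximising the pruning-algorithm likelihood of the tip states, then
#' computes marginal state probabilities for every internal node (the
#' standard re-rooting/outside-pass marginal reconstruction).  A node is
#' flagged `resolved` when its highest marginal probability exceeds 0.51;
#' tips are observed and always resolved.
#'
#' @param tree Rooted `ape::phylo` tree with branch lengths (zero lengths
#'   are floored at 1e-8 for the transition probabilities).  Multifurcations
#'   are resolved deterministically.
#' @param tip_states Named character vector, tip label -> state.
#' @param states Optional ordered state set; defaults to the states observed
#'   at the tips (unobserved states are not imputed).
#' @param root_prior `"uniform"` (default; matches the symmetric ER model)
#'   or `"empirical"` (tip state frequencies).
#' @param rate Optional fixed rate; when supplied no optimisation is done.
#' @param rate_max Upper bracket for the rate search (default scaled to
#'   branch lengths).
#' @return List of class `qs_asr`: `rate`, `log_likelihood`, `states`,
#'   `method = "ER-ML"`, `prob` (node x state marginal probability matrix,
#'   rows = all tips then internal nodes in `ape` numbering), `state`
#'   (argmax state per node), `resolved` (logical per node), `tree`.
#' @export
fit_er_asr <- function(tree, tip_states, states = NULL,
                       root_prior = c("uniform", "empirical"),
                       rate = NULL, rate_max = NULL) {
  root_prior <- match.arg(root_prior)
  prep <- asr_prep(tree, tip_states, states)
  k <- prep$k
  states <- prep$states
  if (k == 1) {
    prob <- matrix(1, prep$n_node, 1, dimnames = list(NULL, states))
    return(structure(list(rate = 0, log_likelihood = 0, states = states,
                          method = "ER-ML", prob = prob,
                          state = rep(states, prep$n_node),
                          resolved = rep(TRUE, prep$n_node), tree = prep$tree),
                     class = "qs_asr"))
  }
  prior <- if (root_prior == "uniform") rep(1 / k, k)
           else as.vector(table(factor(prep$tip_states, levels = states))) /
                prep$n_tip
  if (is.null(rate)) {
    if (is.null(rate_max)) rate_max <- 100 / mean(prep$edge_len)
    f <- function(r) er_loglik(prep, r, prior)
    # the likelihood flattens at high rates, which can defeat a golden-section
    # search over a wide interval: bracket the maximum on a log grid first
    grid <- exp(seq(log(1e-6), log(rate_max), length.out = 16))
    gl <- vapply(grid, f, numeric(1))
    i <- which.max(gl)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
    rate <- opt$maximum
    ll <- opt$objective
  } else {
    ll <- er_loglik(prep, rate, prior)
  }
  ins <- er_inside(prep, rate, prior)
  prob <- er_marginals(prep, rate, prior, ins)
  mx <- max.col(prob, ties.method = "first")
  structure(list(rate = rate, log_likelihood = ll, states = states,
                 method = "ER-ML", prob = prob, state = states[mx],
                 resolved = row_max(prob) > 0.51, tree = prep$tree),
            class = "qs_asr")
}

row_max <- function(m) do.call(pmax, as.data.frame(m))

# Outside pass: marginal probabilities for every node.
er_marginals <- function(prep, rate, prior, ins) {
  k <- prep$k
  n_node <- prep$n_node
  root <- prep$n_tip + 1L
  children <- split(seq_len(nrow(prep$edge)), prep$edge[, 1])
  U <- matrix(NA_real_, n_node, k)
  U[root, ] <- prior
  # pre-order over edges (reverse of postorder)
  pe <- prep$post_edge
  for (i in rev(seq_len(nrow(pe)))) {
    par <- pe[i, 1]; ch <- pe[i, 2]
    eidx <- children[[as.character(par)]]
    this <- eidx[prep$edge[eidx, 2] == ch]
    sibs <- setdiff(eidx, this)
    E <- U[par, ]
    for (s in sibs) E <- E * ins$down[s, ]
    # ER P(t) is symmetric rank-1-plus-identity: t(P) %*% E = off*sum(E) + e*E
    e1 <- exp(-k * rate * prep$edge_len[this])
    u <- (1 - e1) / k * sum(E) + e1 * E
    s <- sum(u)
    U[ch, ] <- if (s > 0) u / s else rep(1 / k, k)
  }
  m <- U * ins$L
  m <- m / rowSums(m)
  colnames(m) <- prep$states
  m[seq_len(prep$n_tip), ] <- ins$L[seq_len(prep$n_tip), ]  # tips observed
  m
}

#' Ancestral states by Fitch parsimony with ACCTRAN resolution
#'
#' Computes the Fitch (unordered, equal-cost) parsimony score of the tip
#' states on a rooted binary tree and one most-parsimonious assignment of
#' internal nodes, resolved by accelerated transformation: the root takes
#' the first state (in state order) of its preliminary set, and each child
#' keeps its parent's state whenever that state is in the child's
#' preliminary set, so changes are committed as close to the root as the
#' preliminary sets allow.
#'
#' @inheritParams fit_er_asr
#' @return List of class `qs_asr`: `score` (parsimony score), `states`,
#'   `method = "ACCTRAN"`, `state` (assignment per node, tips then internal
#'   nodes), `state_sets` (preliminary Fitch sets, logical matrix),
#'   `resolved` (all `TRUE`), `prob` (0/1 matrix for interface parity),
#'   `tree`.
#' @export
acctran_asr <- function(tree, tip_states, states = NULL) {
  prep <- asr_prep(tree, tip_states, states)
  k <- prep$k
  n_node <- prep$n_node
  sets <- matrix(FALSE, n_node, k)
  sets[seq_len(prep$n_tip), ] <- prep$tipL > 0
  score <- 0L
  pe <- prep$post_edge
  # gather children per parent in postorder
  done <- rep(FALSE, n_node)
  kids <- split(pe[, 2], pe[, 1])
  for (i in seq_len(nrow(pe))) {
    par <- pe[i, 1]
    if (done[par]) next
    ch <- kids[[as.character(par)]]
    s <- sets[ch[1], ]
    for (j in ch[-1]) {
      inter <- s & sets[j, ]
      if (any(inter)) s <- inter
      else {
        s <- s | sets[j, ]
        score <- score + 1L
      }
    }
    sets[par, ] <- s
    done[par] <- TRUE
  }
  assign <- integer(n_node)
  root <- prep$n_tip + 1L
  assign[root] <- which(sets[root, ])[1]
  for (i in rev(seq_len(nrow(pe)))) {
    par <- pe[i, 1]; ch <- pe[i, 2]
    if (ch <= prep$n_tip) {
      assign[ch] <- which(sets[ch, ])[1]
    } else if (sets[ch, assign[par]]) {
      assign[ch] <- assign[par]
    } else {
      assign[ch] <- which(sets[ch, ])[1]
    }
  }
  prob <- matrix(0, n_node, k, dimnames = list(NULL, prep$states))
  prob[cbind(seq_len(n_node), assign)] <- 1
  structure(list(score = score, states = prep$states, method = "ACCTRAN",
                 state = prep$states[assign], state_sets = sets,
                 resolved = rep(TRUE, n_node), prob = prob, tree = prep$tree),
            class = "qs_asr")
}

#' @export
print.qs_asr <- function(x, ...) {
  cat("Ancestral QS reconstruction (", x$method, ")\n", sep = "")
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  if (!is.null(x$rate))
    cat(sprintf("  ER rate: %.6g   logLik: %.4f\n", x$rate, x$log_likelihood))
  if (!is.null(x$score)) cat("  parsimony score:", x$score, "\n")
  cat("  resolved nodes:", sum(x$resolved), "/", length(x$resolved), "\n")
  invisible(x)
}
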