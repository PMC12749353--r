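# Independent brute-force oracles used throughout the suite.  They share no
# code with the implementation: likelihoods and marginals by exhaustive
# summation over joint internal-state assignments, parsimony by exhaustive
# minimisation, MAD rooting by a dense grid scan, and the rank-sum null by
# complete enumeration of group splits.

# Random non-ultrametric test tree (rtree: random split topology, uniform
# branch lengths) — independent of the package's Yule simulator.
rand_tree <- function(n_tips, min_len = 0.05, max_len = 1) {
  tr <- ape::rtree(n_tips, br = function(n) stats::runif(n, min_len, max_len))
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

er_pmat_oracle <- function(rate, t, k) {
  q <- matrix(rate, k, k)
  diag(q) <- -(k - 1) * rate
  # matrix exponential by eigen decomposition (symmetric generator)
  ev <- eigen(q, symmetric = TRUE)
  ev$vectors %*% diag(exp(ev$values * t)) %*% t(ev$vectors)
}

# Exhaustive ER likelihood and marginals under a uniform root prior.
brute_er <- function(tree, tip_states, states, rate) {
  k <- length(states)
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) er_pmat_oracle(rate, max(t, 1e-8), k))
  tip_idx <- match(tip_states[tree$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  joint <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    assign <- c(tip_idx, grid[g, ])
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    joint[g] <- pr
  }
  lik <- sum(joint)
  marg <- matrix(0, n_int, k)
  for (j in seq_len(n_int))
    for (s in seq_len(k))
      marg[j, s] <- sum(joint[grid[, j] == s]) / lik
  list(loglik = log(lik), marginals = marg)  # marginals: rows = internal nodes
}

# Exhaustive minimum number of state changes over all joint assignments.
brute_parsimony <- function(tree, tip_states, states) {
  k <- length(states)
  n_tip <- ape::Ntip(tree)
  tip_idx <- match(tip_states[tree$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- c(tip_idx, grid[g, ])
    ch <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# Dense grid scan of the straddling-pair RMS deviation over every branch.
brute_mad <- function(tree, grid_step = 1e-4) {
  tu <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n_tip <- ape::Ntip(tu)
  D <- ape::dist.nodes(tu)
  best <- list(score = Inf, edge = NA, offset = NA)
  for (e in seq_len(nrow(tu$edge))) {
    u <- tu$edge[e, 1]; v <- tu$edge[e, 2]; len <- tu$edge.length[e]
    tips_v <- which(abs(D[seq_len(n_tip), u] - (D[seq_len(n_tip), v] + len)) < 1e-9)
    tips_u <- setdiff(seq_len(n_tip), tips_v)
    if (!length(tips_u) || !length(tips_v)) next
    a <- rep(D[tips_u, u], times = length(tips_v))
    cv <- rep(D[tips_v, v], each = length(tips_u))
    dbc <- a + len + cv
    xs <- unique(c(seq(0, len, by = grid_step), len))
    alpha <- 2 / dbc
    beta <- 2 * a / dbc - 1
    sc <- sqrt(colMeans((outer(alpha, xs) + beta)^2))
    i <- which.min(sc)
    if (sc[i] < best$score)
      best <- list(score = sc[i], edge = e, offset = xs[i])
  }
  best
}

# Exact two-sided rank-sum p-value by enumerating all group splits.
brute_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(ws <= obs)
  p_hi <- mean(ws >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Random tip states with at least two observed states.
rand_states <- function(tree, states) {
  repeat {
    s <- sample(states, ape::Ntip(tree), replace = TRUE)
    if (length(unique(s)) >= 2) break
  }
  stats::setNames(s, tree$tip.label)
}

mini_obo_path <- function() {
  system.file("extdata", "mini_go.obo", package = "qsevo", mustWork = TRUE)
}
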