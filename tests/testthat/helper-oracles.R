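# Independent oracles and fixture builders.  These deliberately avoid the
# package's own code paths: the matrix exponential is a truncated power
# series, epoch segmentation is a plain while-loop, and tree likelihoods
# are exhaustive sums over internal-node state assignments.

# Truncated-series matrix exponential (keep ||M|| modest in fixtures).
oracle_expm <- function(M, nterms = 60) {
  k <- nrow(M)
  out <- diag(k)
  term <- diag(k)
  for (n in seq_len(nterms)) {
    term <- term %*% M / n
    out <- out + term
  }
  out
}

# Epoch index of an age under starts (decreasing, oldest first), youngest
# epoch running to 0; ages beyond the oldest start belong to epoch 1.
oracle_epoch <- function(age, starts) {
  K <- length(starts)
  for (k in seq_len(K)) {
    lo <- if (k == K) 0 else starts[k + 1]
    if (age >= lo && age < starts[k]) return(k)
  }
  if (age >= starts[1]) 1L else K
}

# Parent->child transition matrix across epochs, by stepping down through
# every boundary with the series exponential.
oracle_branch_P <- function(Qs, starts, child_age, parent_age) {
  k <- nrow(Qs[[1]])
  P <- diag(k)
  if (is.null(starts) || length(Qs) == 1) {
    return(oracle_expm(Qs[[1]] * (parent_age - child_age)))
  }
  a <- parent_age
  bounds <- starts[-1]
  while (a > child_age + 1e-15) {
    ep <- oracle_epoch(a - 1e-12, starts)
    lo <- max(child_age, if (ep == length(starts)) 0 else bounds[ep])
    P <- P %*% oracle_expm(Qs[[ep]] * (a - lo))
    a <- lo
  }
  P
}

# Exhaustive likelihood: sum over all internal-node state assignments of
# the product of branch transition probabilities, times the root prior.
oracle_loglik <- function(tree, tip_states, states, Qs, starts, pi) {
  k <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  edge <- tree$edge
  edgeP <- lapply(seq_len(nrow(edge)), function(e)
    oracle_branch_P(Qs, starts, ages[edge[e, 2]], ages[edge[e, 1]]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  assign_state <- function(node, row) {
    if (node <= ntip) match(tip_states[tree$tip.label[node]], states)
    else grid[row, node - ntip]
  }
  full <- matrix(NA_integer_, nrow(grid), ntip + nnode)
  for (node in seq_len(ntip))
    full[, node] <- match(tip_states[tree$tip.label[node]], states)
  full[, (ntip + 1):(ntip + nnode)] <- grid
  lik <- pi[full[, ntip + 1]]
  for (e in seq_len(nrow(edge)))
    lik <- lik * edgeP[[e]][cbind(full[, edge[e, 1]], full[, edge[e, 2]])]
  log(sum(lik))
}

# Exhaustive marginal posterior at every node.
oracle_marginals <- function(tree, tip_states, states, Qs, starts, pi) {
  k <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  edge <- tree$edge
  edgeP <- lapply(seq_len(nrow(edge)), function(e)
    oracle_branch_P(Qs, starts, ages[edge[e, 2]], ages[edge[e, 1]]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  full <- matrix(NA_integer_, nrow(grid), ntip + nnode)
  for (node in seq_len(ntip))
    full[, node] <- match(tip_states[tree$tip.label[node]], states)
  full[, (ntip + 1):(ntip + nnode)] <- grid
  lik <- pi[full[, ntip + 1]]
  for (e in seq_len(nrow(edge)))
    lik <- lik * edgeP[[e]][cbind(full[, edge[e, 1]], full[, edge[e, 2]])]
  pp <- matrix(0, ntip + nnode, k)
  for (node in seq_len(ntip + nnode))
    for (s in seq_len(k))
      pp[node, s] <- sum(lik[full[, node] == s])
  pp / rowSums(pp)
}

# Random generator with off-diagonal rates in (0, maxrate).
rand_q <- function(k, maxrate = 1, states = paste0("s", seq_len(k))) {
  M <- matrix(runif(k * k, 0.05, maxrate), k, k)
  rate_matrix(M, states)
}

# Random small chronogram (coalescent shape, rescaled).
rand_chrono <- function(n, root = NULL) {
  phy <- ape::rcoal(n)
  depth <- max(ape::node.depth.edgelength(phy))
  target <- root %||% runif(1, 1, 3)
  phy$edge.length <- phy$edge.length * target / depth
  as_chronogram(phy)
}

# Random tip states drawn uniformly (guaranteeing no state is impossible).
rand_tips <- function(tree, states) {
  trait_matrix(setNames(sample(states, length(tree$tip.label), replace = TRUE),
                        tree$tip.label), states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
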