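#' Construct a CTMC rate matrix (generator)
#'
#' Off-diagonal entries are instantaneous transition rates in events per
#' Ma; the diagonal is set so each row sums to zero.
#'
#' @param q square numeric matrix of non-negative off-diagonal rates (the
#'   diagonal is ignored and recomputed).
#' @param states character vector of state labels (defaults to existing
#'   dimnames or `s1..sk`).
#' @return a `k x k` generator matrix with dimnames.
#' @export
rate_matrix <- function(q, states = NULL) {
  q <- as.matrix(q)
  if (nrow(q) != ncol(q)) stop("rate matrix must be square")
  k <- nrow(q)
  if (is.null(states)) states <- rownames(q) %||% paste0("s", seq_len(k))
  if (length(states) != k) stop("'states' must have one label per state")
  diag(q) <- 0
  if (any(q < 0)) stop("off-diagonal rates must be >= 0")
  diag(q) <- -rowSums(q)
  dimnames(q) <- list(states, states)
  q
}

#' Stationary distribution of a generator
#'
#' Solves \eqn{\pi Q = 0} with \eqn{\sum \pi = 1} by least squares.
#'
#' @param Q a generator matrix (rows sum to 0).
#' @return numeric probability vector.
#' @export
stationary_dist <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- as.numeric(qr.solve(A, b))
  p[p < 0] <- 0
  p / sum(p)
}

#' Build a CTMC rate model
#'
#' A rate model bundles the state alphabet, either a single
#' time-homogeneous generator or a per-epoch schedule of generators, and a
#' root-state prior.  Epoch-stratified models change generator at fixed
#' ages (epoch boundaries); branches crossing a boundary are split there.
#'
#' @param Q a generator matrix, or a list of generators (oldest epoch
#'   first) for an epoch-stratified model.
#' @param epochs for stratified models: a [paleo_structure()] or a numeric
#'   vector of epoch start ages (Ma, decreasing, oldest first; the
#'   youngest epoch runs to 0).
#' @param root_prior `"flat"` (default), `"stationary"` (stationary
#'   distribution of the oldest epoch's generator), or a numeric
#'   probability vector over states.
#' @param states state labels; defaults to the generator's dimnames.
#' @return an object of class `"rate_model"`.
#' @export
rate_model <- function(Q, epochs = NULL, root_prior = "flat", states = NULL) {
  Qs <- if (is.list(Q)) Q else list(Q)
  Qs <- lapply(Qs, rate_matrix, states = states)
  k <- nrow(Qs[[1]])
  if (any(vapply(Qs, nrow, 0L) != k))
    stop("all epoch generators must share one state space")
  states <- rownames(Qs[[1]])
  epoch_starts <- NULL
  if (length(Qs) > 1 || !is.null(epochs)) {
    if (is.null(epochs)) stop("a generator schedule needs 'epochs'")
    epoch_starts <- if (inherits(epochs, "paleo_structure"))
      epochs$epochs$start else sort(as.numeric(epochs), decreasing = TRUE)
    if (length(epoch_starts) != length(Qs))
      stop("need exactly one generator per epoch")
  }
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("flat", "stationary"))
    pi <- if (root_prior == "flat") rep(1 / k, k) else stationary_dist(Qs[[1]])
  } else {
    pi <- as.numeric(root_prior)
    if (length(pi) != k || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
      stop("numeric root prior must be a length-k probability vector")
  }
  structure(list(states = states, Qs = Qs, epoch_starts = epoch_starts,
                 root_prior = stats::setNames(pi, states)),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("CTMC rate model: %d states (%s), %s\n",
              length(x$states), paste(x$states, collapse = ", "),
              if (length(x$Qs) == 1) "time-homogeneous"
              else sprintf("%d epochs", length(x$Qs))))
  invisible(x)
}

#' Transition probability matrix over a duration
#'
#' Computes \eqn{P = \exp(Qt)} by a dense scaling-and-squaring matrix
#' exponential.
#'
#' @param Q a generator matrix.
#' @param t duration in Ma (must be `>= 0`).
#' @return stochastic matrix (rows sum to 1).
#' @export
transition_probs <- function(Q, t) {
  if (t < 0) stop("'t' must be >= 0")
  P <- cpp_expm(as.matrix(Q) * t)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Split the interval [child_age, parent_age] at the interior epoch
# boundaries it crosses.  Returns a list with `epoch` (index, oldest
# segment first) and `dt`; multiplication of per-segment exponentials in
# this order gives the parent->child transition matrix.
.branch_segments <- function(child_age, parent_age, epoch_starts) {
  if (is.null(epoch_starts) || length(epoch_starts) <= 1)
    return(list(epoch = 1L, dt = parent_age - child_age))
  K <- length(epoch_starts)
  bounds <- epoch_starts[-1]            # interior boundaries, oldest first
  cuts <- bounds[bounds > child_age & bounds < parent_age]
  pts <- c(parent_age, cuts, child_age) # decreasing ages
  upper <- pts[-length(pts)]
  lower <- pts[-1]
  list(epoch = epoch_index(epoch_starts, (upper + lower) / 2),
       dt = upper - lower)
}

#' Transition probabilities along a branch crossing epoch boundaries
#'
#' The branch is split at every epoch boundary it crosses and the
#' per-segment matrix exponentials are multiplied in order from the parent
#' (older) end to the child (younger) end; the product does not commute,
#' so the orientation is part of the contract.  Row `i`, column `j` is the
#' probability that a lineage in state `i` at the parent ends in state `j`
#' at the child.
#'
#' @param model a [rate_model()] (a time-homogeneous model collapses to
#'   [transition_probs()]).
#' @param child_age,parent_age ages in Ma, `parent_age >= child_age`.
#' @return stochastic matrix.
#' @export
branch_prob_piecewise <- function(model, child_age, parent_age) {
  stopifnot(inherits(model, "rate_model"))
  if (parent_age < child_age) stop("'parent_age' must be >= 'child_age'")
  seg <- .branch_segments(child_age, parent_age, model$epoch_starts)
  k <- length(model$states)
  P <- diag(k)
  for (i in seq_along(seg$epoch))
    P <- P %*% transition_probs(model$Qs[[seg$epoch[i]]], seg$dt[i])
  dimnames(P) <- list(model$states, model$states)
  P
}

# Precompute everything about (tree, model-structure, traits) that does
# not depend on rate values: postorder edges, per-edge epoch segments, tip
# partials, root index.  MCMC reuses this across iterations with fresh
# generator cubes.
.ctmc_prep <- function(tree, traits, model) {
  if (!identical(as.character(traits$alphabet), as.character(model$states)))
    stop("trait alphabet must equal model states (same order)")
  stratified <- !is.null(model$epoch_starts) && length(model$Qs) > 1
  ages <- .tree_ages(tree, need_ultrametric = stratified)
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  m <- nrow(edge)
  segs <- vector("list", m)
  for (e in seq_len(m))
    segs[[e]] <- .branch_segments(ages[edge[e, 2]], ages[edge[e, 1]],
                                  model$epoch_starts)
  list(edge = edge,
       nseg = vapply(segs, function(s) length(s$epoch), 0L),
       seg_epoch = unlist(lapply(segs, `[[`, "epoch")),
       seg_dt = unlist(lapply(segs, `[[`, "dt")),
       init = .tip_partials(tree, traits),
       root = length(tree$tip.label) + 1L,
       ntip = length(tree$tip.label),
       ages = ages,
       states = model$states)
}

# Fast path: likelihood for a prepared tree under a fresh generator cube.
.ctmc_eval <- function(prep, Qs, pi, want = 0L) {
  k <- nrow(Qs[[1]])
  cube <- array(unlist(Qs), dim = c(k, k, length(Qs)))
  cpp_ctmc(prep$edge, prep$nseg, prep$seg_epoch, prep$seg_dt, cube,
           prep$init, prep$root, pi, as.integer(want))
}

#' Pruning log-likelihood of a discrete character on a chronogram
#'
#' Felsenstein pruning with per-edge rescaling; branches are split at
#' epoch boundaries for stratified models and the root is summed under the
#' model's root prior.
#'
#' @param tree a [as_chronogram()] chronogram (a plain rooted `phylo` is
#'   accepted for time-homogeneous models).
#' @param traits a [trait_matrix()] covering every tip (`"?"` allowed).
#' @param model a [rate_model()].
#' @return an object of class `"likelihood_result"`: list with `loglik`
#'   and `partials` (per-node rescaled partial likelihood vectors, rows in
#'   node order, entries in `[0, 1]`).
#' @export
prune_likelihood <- function(tree, traits, model) {
  stopifnot(inherits(model, "rate_model"))
  if (!setequal(intersect(traits$alphabet, model$states), traits$alphabet))
    stop("trait alphabet does not match model states")
  if (!identical(traits$alphabet, model$states))
    stop("trait alphabet must equal model states (same order)")
  prep <- .ctmc_prep(tree, traits, model)
  res <- .ctmc_eval(prep, model$Qs, model$root_prior, want = 1L)
  structure(list(loglik = res$loglik,
                 partials = `dimnames<-`(res$partials,
                                         list(NULL, model$states)),
                 states = model$states),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("CTMC pruning log-likelihood: %.6f\n", x$loglik))
  invisible(x)
}

# Upward partials + per-edge transition matrices, shared by the marginal
# and mapping machinery.
.ctmc_updown <- function(tree, traits, model) {
  prep <- .ctmc_prep(tree, traits, model)
  res <- .ctmc_eval(prep, model$Qs, model$root_prior, want = 2L)
  list(prep = prep, loglik = res$loglik, F = res$partials,
       edgeP = res$edgeP, pi = model$root_prior)
}

# Downward ("above") pass: A[root] = pi; for edge (u,v),
# A[v] = t(P_uv) (A[u] * prod_{w sibling of v} P_uw F_w).
# Marginal posterior at v is proportional to A[v] * F[v].
.down_pass <- function(ud) {
  edge <- ud$prep$edge
  m <- nrow(edge)
  k <- ncol(ud$F)
  N <- nrow(ud$F)
  C <- matrix(NA_real_, m, k)      # C[e, ] = P_e F_child(e)
  for (e in seq_len(m))
    C[e, ] <- ud$edgeP[, , e] %*% ud$F[edge[e, 2], ]
  A <- matrix(NA_real_, N, k)
  A[ud$prep$root, ] <- ud$pi
  kids <- split(seq_len(m), edge[, 1])
  for (e in rev(seq_len(m))) {     # reverse postorder = preorder
    u <- edge[e, 1]; v <- edge[e, 2]
    sibs <- setdiff(kids[[as.character(u)]], e)
    w <- A[u, ]
    for (s in sibs) w <- w * C[s, ]
    av <- as.numeric(crossprod(ud$edgeP[, , e], w))
    tot <- sum(av)
    A[v, ] <- if (tot > 0) av / tot else av
  }
  A
}

#' Marginal ancestral state probabilities
#'
#' Per-node marginal posterior state probabilities from a combined
#' upward/downward pass, with the maximum a posteriori (MAP) state and --
#' when the MAP posterior probability falls below `split_pp` -- the
#' second-ranked state (the "split circle" reporting rule).  Ties in the
#' MAP state are broken by alphabet order.
#'
#' @inheritParams prune_likelihood
#' @param split_pp threshold below which the second-ranked state is
#'   reported (default 0.9).
#' @return list with `pp` (node x state probability matrix), `summary`
#'   (data.frame: node, state, pp, second_state, second_pp, split) and
#'   `loglik`.
#' @export
marginal_ancestral <- function(tree, traits, model, split_pp = 0.9) {
  ud <- .ctmc_updown(tree, traits, model)
  if (!is.finite(ud$loglik))
    stop("data have zero likelihood under this model")
  A <- .down_pass(ud)
  pp <- A * ud$F
  pp <- pp / rowSums(pp)
  colnames(pp) <- model$states
  list(pp = pp, summary = .pp_summary(pp, tree, model$states, split_pp),
       loglik = ud$loglik)
}

# Shared MAP/split-rule summary table from a node x state PP matrix.
.pp_summary <- function(pp, tree, states, split_pp) {
  ntip <- length(tree$tip.label)
  node <- c(tree$tip.label, paste0("node", (ntip + 1):(ntip + tree$Nnode)))
  map_i <- apply(pp, 1, which.max)           # first max = alphabet order
  sec <- t(apply(pp, 1, function(p) {
    o <- order(-p, seq_along(p))
    c(o[2], p[o[2]])
  }))
  data.frame(node = node,
             state = states[map_i],
             pp = pp[cbind(seq_len(nrow(pp)), map_i)],
             second_state = ifelse(pp[cbind(seq_len(nrow(pp)), map_i)] <
                                     split_pp, states[sec[, 1]], NA),
             second_pp = ifelse(pp[cbind(seq_len(nrow(pp)), map_i)] <
                                  split_pp, sec[, 2], NA),
             split = pp[cbind(seq_len(nrow(pp)), map_i)] < split_pp,
             row.names = NULL)
}

#' Write marginal posterior probabilities as TSV
#'
#' Long format: one row per node-state pair (`node_id`, `state`, `pp`).
#'
#' @param pp node x state probability matrix (as returned in
#'   `marginal_ancestral()$pp`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_node_pp <- function(pp, path) {
  df <- data.frame(node_id = rep(seq_len(nrow(pp)), ncol(pp)),
                   state = rep(colnames(pp), each = nrow(pp)),
                   pp = as.numeric(pp))
  utils::write.table(df[order(df$node_id), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
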