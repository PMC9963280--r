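# Stochastic character mapping: sample full character histories (node
# states plus event times along branches) conditional on tip data and a
# rate model.  Branch histories use forward rejection sampling with a
# uniformization bridge fallback so sampling terminates even on long
# branches with incompatible-looking endpoint constraints.

# Vectorised joint node-state sampling for n independent draws, given the
# upward partials F and per-edge transition matrices.  Returns an
# (ntip+nnode) x n integer matrix of state indices.
.sample_node_states <- function(ud, n) {
  edge <- ud$prep$edge
  k <- ncol(ud$F)
  N <- nrow(ud$F)
  out <- matrix(NA_integer_, N, n)
  w <- ud$pi * ud$F[ud$prep$root, ]
  out[ud$prep$root, ] <- sample.int(k, n, replace = TRUE, prob = w)
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    u <- edge[e, 1]; v <- edge[e, 2]
    P <- ud$edgeP[, , e]
    pu <- out[u, ]
    for (i in seq_len(k)) {
      idx <- which(pu == i)
      if (!length(idx)) next
      wv <- P[i, ] * ud$F[v, ]
      if (sum(wv) <= 0)
        stop("zero-probability node configuration; data impossible under model")
      out[v, idx] <- sample.int(k, length(idx), replace = TRUE, prob = wv)
    }
  }
  out
}

# Forward Gillespie path across piecewise-constant generators; `segs` is
# the oldest-first segment list for one branch.  Returns end state and
# events (time measured from the parent end).
.gillespie_branch <- function(start, segs, Qs) {
  s <- start
  t0 <- 0
  ev_t <- numeric(0); ev_from <- integer(0); ev_to <- integer(0)
  for (i in seq_along(segs$epoch)) {
    Q <- Qs[[segs$epoch[i]]]
    dt <- segs$dt[i]
    tau <- 0
    repeat {
      lam <- -Q[s, s]
      if (lam <= 0) break
      e <- stats::rexp(1, lam)
      if (tau + e > dt) break
      tau <- tau + e
      p <- Q[s, ]; p[s] <- 0
      ns <- sample.int(length(p), 1, prob = p)
      ev_t <- c(ev_t, t0 + tau); ev_from <- c(ev_from, s); ev_to <- c(ev_to, ns)
      s <- ns
    }
    t0 <- t0 + dt
  }
  list(end = s, t = ev_t, from = ev_from, to = ev_to)
}

# Uniformization bridge: sample a path of a homogeneous CTMC of duration t
# conditioned on endpoints (a, b).  Jump count is drawn from the
# uniformized Poisson mixture, interior states from the discrete bridge of
# R = I + Q/mu, and virtual (self) jumps are discarded.
.uniformization_bridge <- function(Q, t, a, b) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu * t <= 0) {
    if (a != b) stop("impossible endpoint pair on a zero-rate segment")
    return(list(t = numeric(0), from = integer(0), to = integer(0)))
  }
  R <- diag(k) + Q / mu
  nmax <- max(20, ceiling(mu * t + 12 * sqrt(mu * t) + 20))
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (i in seq_len(nmax)) Rpow[[i + 1]] <- Rpow[[i]] %*% R
  lw <- vapply(0:nmax, function(n)
    stats::dpois(n, mu * t, log = TRUE) + log(max(Rpow[[n + 1]][a, b], 0)),
    0)
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) stop("impossible endpoint pair under model")
  n <- sample.int(nmax + 1, 1, prob = w) - 1L
  states <- integer(n + 1); states[1] <- a
  if (n > 0) {
    for (j in seq_len(n - 1)) {
      pj <- R[states[j], ] * vapply(seq_len(k), function(s)
        Rpow[[n - j + 1]][s, b], 0)
      states[j + 1] <- sample.int(k, 1, prob = pj)
    }
    states[n + 1] <- b
    times <- sort(stats::runif(n, 0, t))
    keep <- which(states[-1] != states[-(n + 1)])
    return(list(t = times[keep], from = states[keep], to = states[keep + 1]))
  }
  list(t = numeric(0), from = integer(0), to = integer(0))
}

# Sample one branch history conditioned on endpoint states.  Rejection
# sampling against the forward process, then (after `max_reject`
# attempts) segment-wise uniformization with interior boundary states
# drawn from the segment-product bridge.
.sample_branch_history <- function(start, end, segs, Qs, max_reject = 1000) {
  for (r in seq_len(max_reject)) {
    path <- .gillespie_branch(start, segs, Qs)
    if (path$end == end) return(path[c("t", "from", "to")])
  }
  S <- length(segs$epoch)
  Plist <- lapply(seq_len(S), function(i)
    transition_probs(Qs[[segs$epoch[i]]], segs$dt[i]))
  suffix <- vector("list", S + 1)        # suffix[[i]] = P_i ... P_S
  suffix[[S + 1]] <- diag(nrow(Qs[[1]]))
  for (i in rev(seq_len(S))) suffix[[i]] <- Plist[[i]] %*% suffix[[i + 1]]
  bstates <- integer(S + 1)
  bstates[1] <- start; bstates[S + 1] <- end
  if (S > 1) {
    for (i in seq_len(S - 1)) {
      p <- Plist[[i]][bstates[i], ] * suffix[[i + 1]][, end]
      bstates[i + 1] <- sample.int(length(p), 1, prob = p)
    }
  }
  t0 <- 0
  ev_t <- numeric(0); ev_from <- integer(0); ev_to <- integer(0)
  for (i in seq_len(S)) {
    br <- .uniformization_bridge(Qs[[segs$epoch[i]]], segs$dt[i],
                                 bstates[i], bstates[i + 1])
    ev_t <- c(ev_t, t0 + br$t)
    ev_from <- c(ev_from, br$from); ev_to <- c(ev_to, br$to)
    t0 <- t0 + segs$dt[i]
  }
  list(t = ev_t, from = ev_from, to = ev_to)
}

#' Stochastic character mapping
#'
#' Samples full character histories conditional on the tip data and a
#' fixed rate model: joint node states from the conditional distribution
#' given by the pruning partials, then per-branch event histories
#' conditioned on the branch's endpoint states (forward rejection
#' sampling, with a uniformization bridge after `max_reject` failed
#' attempts).  Event times are reported as ages in Ma; events lie strictly
#' between the child and parent ages of their branch.
#'
#' @inheritParams prune_likelihood
#' @param seed integer seed for reproducibility (optional).
#' @param nmaps number of independent maps to draw.
#' @param full_history if `FALSE`, only node states are sampled (much
#'   faster; sufficient for ancestral-state summaries).
#' @param max_reject rejection-sampling cap per branch before switching to
#'   the uniformization bridge.
#' @return a single `"stochastic_map"` (when `nmaps = 1`) or a list of
#'   them.  Each map holds `node_states` (state labels per node) and
#'   `events` (data.frame: edge, age, from, to).
#' @export
stochastic_map <- function(tree, traits, model, seed = NULL, nmaps = 1,
                           full_history = TRUE, max_reject = 1000) {
  if (!is.null(seed)) set.seed(seed)
  ud <- .ctmc_updown(tree, traits, model)
  if (!is.finite(ud$loglik))
    stop("data have zero likelihood under this model (cannot map)")
  ns <- .sample_node_states(ud, nmaps)
  maps <- lapply(seq_len(nmaps), function(j)
    .one_map(ud, ns[, j], model, full_history, max_reject, tree))
  if (nmaps == 1) maps[[1]] else maps
}

.one_map <- function(ud, node_state, model, full_history, max_reject, tree) {
  edge <- ud$prep$edge
  ev <- NULL
  if (full_history) {
    rows <- vector("list", nrow(edge))
    for (e in seq_len(nrow(edge))) {
      u <- edge[e, 1]; v <- edge[e, 2]
      segs <- list(epoch = ud$prep$seg_epoch[.seg_range(ud$prep, e)],
                   dt = ud$prep$seg_dt[.seg_range(ud$prep, e)])
      h <- .sample_branch_history(node_state[u], node_state[v], segs,
                                  model$Qs, max_reject)
      if (length(h$t))
        rows[[e]] <- data.frame(edge = e,
                                age = ud$prep$ages[u] - h$t,
                                from = model$states[h$from],
                                to = model$states[h$to])
    }
    ev <- do.call(rbind, rows)
    if (is.null(ev))
      ev <- data.frame(edge = integer(0), age = numeric(0),
                       from = character(0), to = character(0))
  }
  structure(list(
    node_states = stats::setNames(model$states[node_state],
                                  c(tree$tip.label,
                                    paste0("node", ud$prep$root:(nrow(ud$F))))),
    events = ev,
    edge = edge,
    states = model$states,
    loglik = ud$loglik),
    class = "stochastic_map")
}

.seg_range <- function(prep, e) {
  ends <- cumsum(prep$nseg)
  starts <- c(1L, ends[-length(ends)] + 1L)
  starts[e]:ends[e]
}

#' @export
print.stochastic_map <- function(x, ...) {
  nev <- if (is.null(x$events)) NA_integer_ else nrow(x$events)
  cat(sprintf("Stochastic map: %d nodes, %s events\n",
              length(x$node_states),
              if (is.na(nev)) "node states only, no" else nev))
  invisible(x)
}

#' Serialize stochastic maps as SIMMAP-style annotated Newick
#'
#' Each branch is annotated `{state,duration:state,duration...}` from the
#' rootward end of the branch to the tipward end.
#'
#' @param map a `"stochastic_map"` (with full branch histories).
#' @param tree the chronogram the map was drawn on.
#' @param path output path; if `NULL` the string is returned.
#' @return the path (or the SIMMAP string when `path = NULL`), invisibly.
#' @export
write_simmap <- function(map, tree, path = NULL) {
  stopifnot(inherits(map, "stochastic_map"))
  if (is.null(map$events))
    stop("map has no branch histories; rerun with full_history = TRUE")
  ages <- .tree_ages(tree, need_ultrametric = FALSE)
  edge <- map$edge
  ntip <- length(tree$tip.label)
  seg_str <- function(e) {
    u <- edge[e, 1]; v <- edge[e, 2]
    evs <- map$events[map$events$edge == e, , drop = FALSE]
    evs <- evs[order(-evs$age), , drop = FALSE]   # rootward first
    st <- c(map$node_states[u], evs$to)
    bounds <- c(ages[u], evs$age, ages[v])
    paste(sprintf("%s,%.8g", st, bounds[-length(bounds)] - bounds[-1]),
          collapse = ":")
  }
  children <- split(seq_len(nrow(edge)), edge[, 1])
  build <- function(node) {
    es <- children[[as.character(node)]]
    if (is.null(es)) return(tree$tip.label[node])
    inner <- vapply(es, function(e)
      paste0(build(edge[e, 2]), ":{", seg_str(e), "}"), "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  s <- paste0(build(ntip + 1L), ";")
  if (is.null(path)) return(invisible(s))
  writeLines(s, path)
  invisible(path)
}
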