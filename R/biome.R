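# Paleobiome-informed biome-shift model: a CTMC over composite
# (area, biome) states whose dispersal and biome-shift rates mix an
# uninformed graph, a per-epoch paleogeographic adjacency graph, and a
# per-epoch paleobiome availability graph with simplex weights
# (w_u, w_g, w_b).

#' Composite (area, biome) state labels
#'
#' States are flattened area-major: state index
#' `(area - 1) * n_biomes + biome`, labelled `"area:biome"`.
#'
#' @param paleo a [paleo_structure()].
#' @return character vector of composite state labels.
#' @export
composite_states <- function(paleo) {
  as.vector(t(outer(paleo$areas, paleo$biomes, paste, sep = ":")))
}

#' Biome-shift model parameters
#'
#' @param delta base dispersal rate (events per Ma, > 0).
#' @param beta base biome-shift rate (events per Ma, > 0).
#' @param w weight simplex `c(w_u, w_g, w_b)`: relative dependence on the
#'   uninformed, paleogeographic, and paleobiome rate graphs; must be
#'   non-negative and sum to 1.
#' @return a list of class `"biome_params"` (adds `w_not_b = 1 - w_b`).
#' @export
biome_params <- function(delta, beta, w) {
  if (!(delta > 0 && beta > 0)) stop("'delta' and 'beta' must be > 0")
  w <- as.numeric(w)
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("'w' must be a length-3 simplex (w_u, w_g, w_b)")
  structure(list(delta = delta, beta = beta,
                 w = stats::setNames(w, c("w_u", "w_g", "w_b")),
                 w_not_b = 1 - w[3]),
            class = "biome_params")
}

# Index scaffolding for fast composite-Q assembly: positions and
# (area, biome) coordinates of every admissible single-event transition,
# plus the per-epoch graph values each one reads.
.composite_index <- function(paleo) {
  nA <- length(paleo$areas); nB <- length(paleo$biomes)
  K <- nrow(paleo$epochs)
  st <- expand.grid(biome = seq_len(nB), area = seq_len(nA))[, c("area", "biome")]
  n <- nA * nB
  idx <- function(a, b) (a - 1L) * nB + b
  # dispersal: (a,b) -> (a2,b), a2 != a
  dg <- expand.grid(i = seq_len(n), a2 = seq_len(nA))
  dg$a <- st$area[dg$i]; dg$b <- st$biome[dg$i]
  dg <- dg[dg$a2 != dg$a, ]
  dg$j <- idx(dg$a2, dg$b)
  # biome shift: (a,b) -> (a,b2), b2 != b
  bg <- expand.grid(i = seq_len(n), b2 = seq_len(nB))
  bg$a <- st$area[bg$i]; bg$b <- st$biome[bg$i]
  bg <- bg[bg$b2 != bg$b, ]
  bg$j <- idx(bg$a, bg$b2)
  list(n = n,
       disp = dg[c("i", "j", "a", "a2", "b")],
       biome = bg[c("i", "j", "a", "b2")],
       gvals = lapply(seq_len(K), function(k)
         paleo$geo_adjacency[[k]][cbind(dg$a, dg$a2)]),
       bvals_disp = lapply(seq_len(K), function(k)
         paleo$biome_availability[[k]][cbind(dg$a2, dg$b)]),
       bvals_biome = lapply(seq_len(K), function(k)
         paleo$biome_availability[[k]][cbind(bg$a, bg$b2)]))
}

.composite_q_from_index <- function(ci, params, k) {
  w <- params$w
  Q <- matrix(0, ci$n, ci$n)
  Q[cbind(ci$disp$i, ci$disp$j)] <- params$delta *
    (w[1] + w[2] * ci$gvals[[k]] + w[3] * ci$bvals_disp[[k]])
  Q[cbind(ci$biome$i, ci$biome$j)] <- params$beta *
    (w[1] + w[2] + w[3] * ci$bvals_biome[[k]])
  diag(Q) <- -rowSums(Q)
  Q
}

#' Composite-state generator for one epoch
#'
#' Event rates mix three graphs under a shared weight simplex.  A
#' dispersal event `(a, b) -> (a', b)` has rate
#' `delta * (w_u + w_g * G_k[a, a'] + w_b * B_k[a', b])`: the uninformed
#' component ignores geography, the paleogeographic component reads the
#' epoch's area adjacency, and the paleobiome component asks whether the
#' lineage's current biome is available in the destination area.  A
#' biome-shift event `(a, b) -> (a, b')` has rate
#' `beta * (w_u + w_g + w_b * B_k[a, b'])`: only the paleobiome component
#' is informative for in-place biome shifts.  Simultaneous area and biome
#' change is disallowed (rate 0).
#'
#' @param params a [biome_params()].
#' @param paleo a [paleo_structure()].
#' @param epoch epoch index (1 = oldest).
#' @return generator matrix over [composite_states()].
#' @export
build_composite_q <- function(params, paleo, epoch) {
  stopifnot(inherits(params, "biome_params"),
            inherits(paleo, "paleo_structure"))
  K <- nrow(paleo$epochs)
  if (!(epoch %in% seq_len(K))) stop("invalid epoch index: ", epoch)
  ci <- .composite_index(paleo)
  Q <- .composite_q_from_index(ci, params, epoch)
  dimnames(Q) <- list(composite_states(paleo), composite_states(paleo))
  Q
}

#' Epoch-stratified rate model over composite states
#'
#' @inheritParams build_composite_q
#' @param root_prior as in [rate_model()].
#' @return a [rate_model()] with one generator per epoch.
#' @export
biome_rate_model <- function(params, paleo, root_prior = "flat") {
  Qs <- lapply(seq_len(nrow(paleo$epochs)), build_composite_q,
               params = params, paleo = paleo)
  rate_model(Qs, epochs = paleo, root_prior = root_prior)
}

#' Read a taxon / area / biome tip table
#'
#' TSV (or CSV) with header columns `taxon`, `area`, `biome`; converted
#' to a trait matrix over the composite alphabet.
#'
#' @param path path to the table.
#' @param paleo a [paleo_structure()] providing areas and biomes.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return a [trait_matrix()] over [composite_states()].
#' @export
read_biome_tips <- function(path, paleo, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "area", "biome") %in% names(df)))
    stop("tip table must have header columns taxon, area, biome")
  bad <- which(!(df$area %in% paleo$areas))
  if (length(bad)) stop("unknown area at row(s) ", paste(bad, collapse = ", "))
  bad <- which(!(df$biome %in% paleo$biomes))
  if (length(bad)) stop("unknown biome at row(s) ", paste(bad, collapse = ", "))
  trait_matrix(stats::setNames(paste(df$area, df$biome, sep = ":"), df$taxon),
               composite_states(paleo), name = "biome_area")
}

#' MCMC over the biome-shift model
#'
#' Metropolis-Hastings sampling of the base dispersal rate `delta`, base
#' biome-shift rate `beta` (log-scale multiplier moves, exponential
#' priors) and the weight simplex (Dirichlet proposal centred on the
#' current weights; flat Dirichlet(1,1,1) prior), with the likelihood
#' computed by epoch-stratified pruning on the composite alphabet.  Each
#' iteration performs one randomly chosen move.
#'
#' With `rj_wb = TRUE` an indicator `z` with equal prior odds pins
#' `w_b` to 0 (paleobiome independence); the dimension jump draws the new
#' `w_b` from its conditional prior (Beta(1,2)), so the acceptance ratio
#' is the likelihood ratio, and the Bayes factor for paleobiome
#' dependence follows the indicator-count formula.
#'
#' @param tree a chronogram.
#' @param tip_states a [trait_matrix()] over [composite_states()].
#' @param paleo a [paleo_structure()].
#' @param iterations total iterations (default 25000).
#' @param burn_in fraction of `iterations` (default 0.06) or a count.
#' @param seed integer seed.
#' @param delta_prior_mean,beta_prior_mean exponential prior means;
#'   default `10 / sum(tree$edge.length)`.
#' @param rj_wb enable the paleobiome-independence indicator.
#' @param likelihood set `FALSE` for a prior-only run.
#' @param root_prior as in [rate_model()].
#' @param concentration Dirichlet proposal concentration.
#' @param tune width of the log-multiplier rate moves.
#' @return object of class `"biome_trace"`: list with `pars`
#'   (iteration, loglik, logpost, delta, beta, w_u, w_g, w_b, z),
#'   `paleo`, `burn_in`, `iterations`, `seed`.
#' @export
biome_mcmc <- function(tree, tip_states, paleo, iterations = 25000,
                       burn_in = 0.06, seed = NULL,
                       delta_prior_mean = NULL, beta_prior_mean = NULL,
                       rj_wb = FALSE, likelihood = TRUE,
                       root_prior = "flat", concentration = 50, tune = 1.5) {
  stopifnot(inherits(paleo, "paleo_structure"))
  burn <- if (burn_in < 1) floor(burn_in * iterations) else as.integer(burn_in)
  if (burn >= iterations) stop("'iterations' must exceed burn-in")
  treelen <- sum(tree$edge.length)
  md <- delta_prior_mean %||% (10 / treelen)
  mb <- beta_prior_mean %||% (10 / treelen)
  ci <- .composite_index(paleo)
  K <- nrow(paleo$epochs)
  dummy <- biome_rate_model(biome_params(1, 1, c(1, 0, 0) / 1), paleo,
                            root_prior = root_prior)
  prep <- .ctmc_prep(tree, tip_states, dummy)
  pi <- dummy$root_prior
  n <- ci$n
  ll_fun <- if (likelihood) {
    function(par) {
      Qs <- lapply(seq_len(K), function(k)
        .composite_q_from_index(ci, par, k))
      cube <- array(unlist(Qs), dim = c(n, n, K))
      cpp_ctmc(prep$edge, prep$nseg, prep$seg_epoch, prep$seg_dt, cube,
               prep$init, prep$root, pi, 0L)$loglik
    }
  } else function(par) 0

  if (!is.null(seed)) set.seed(seed)
  par <- list(delta = stats::rexp(1, 1 / md), beta = stats::rexp(1, 1 / mb),
              w = .rdirichlet(c(1, 1, 1)))
  z <- 1L
  ll <- ll_fun(par)
  tries <- 0
  while (!is.finite(ll) && tries < 50) {
    par$delta <- stats::rexp(1, 1 / md); par$beta <- stats::rexp(1, 1 / mb)
    par$w <- .rdirichlet(c(1, 1, 1))
    ll <- ll_fun(par)
    tries <- tries + 1
  }
  if (!is.finite(ll))
    stop("impossible tip configuration: likelihood is zero for 50 prior draws")

  out <- matrix(NA_real_, iterations, 8,
                dimnames = list(NULL, c("loglik", "logpost", "delta", "beta",
                                        "w_u", "w_g", "w_b", "z")))
  lprior <- function(par)
    stats::dexp(par$delta, 1 / md, log = TRUE) +
    stats::dexp(par$beta, 1 / mb, log = TRUE)
  for (it in seq_len(iterations)) {
    mv <- sample.int(if (rj_wb) 4L else 3L, 1)
    if (mv <= 2) {                       # scale delta or beta
      f <- exp(tune * (stats::runif(1) - 0.5))
      p2 <- par
      if (mv == 1) p2$delta <- par$delta * f else p2$beta <- par$beta * f
      ll2 <- ll_fun(p2)
      la <- (ll2 - ll) + lprior(p2) - lprior(par) + log(f)
      if (log(stats::runif(1)) < la) { par <- p2; ll <- ll2 }
    } else if (mv == 3) {                # Dirichlet move on the weights
      free <- if (z == 1L) 1:3 else 1:2
      wcur <- par$w[free]
      a_fwd <- concentration * wcur + 0.5
      wnew <- .rdirichlet(a_fwd)
      a_rev <- concentration * wnew + 0.5
      p2 <- par
      p2$w[free] <- wnew
      if (z == 0L) p2$w[3] <- 0
      ll2 <- ll_fun(p2)
      la <- (ll2 - ll) +
        .ddirichlet_log(wcur, a_rev) - .ddirichlet_log(wnew, a_fwd)
      if (log(stats::runif(1)) < la) { par <- p2; ll <- ll2 }
    } else {                             # rj toggle on w_b
      if (z == 1L) {                     # death: pin w_b to 0
        p2 <- par
        wb <- par$w[3]
        if (wb < 1) {
          p2$w <- c(par$w[1], par$w[2], 0) / (1 - wb)
          p2$w[3] <- 0
          ll2 <- ll_fun(p2)
          if (log(stats::runif(1)) < ll2 - ll) { par <- p2; ll <- ll2; z <- 0L }
        }
      } else {                           # birth: draw w_b from Beta(1,2)
        wb <- stats::rbeta(1, 1, 2)
        p2 <- par
        p2$w <- c(par$w[1] * (1 - wb), par$w[2] * (1 - wb), wb)
        ll2 <- ll_fun(p2)
        if (log(stats::runif(1)) < ll2 - ll) { par <- p2; ll <- ll2; z <- 1L }
      }
    }
    out[it, ] <- c(ll,
                   ll + lprior(par),
                   par$delta, par$beta, par$w, z)
  }
  pars <- data.frame(iteration = seq_len(iterations), out)
  structure(list(pars = pars, paleo = paleo, burn_in = burn,
                 iterations = iterations, seed = seed, rj_wb = rj_wb,
                 delta_prior_mean = md, beta_prior_mean = mb,
                 root_prior = root_prior),
            class = "biome_trace")
}

#' Posterior summary of a biome-shift trace
#'
#' Mean, median and 95% HPD per statistic (`w_u`, `w_g`, `w_b`,
#' `w_not_b`, `delta`, `beta`), in the usual published layout.
#'
#' @param trace a `"biome_trace"` from [biome_mcmc()].
#' @param mass HPD mass.
#' @return data.frame with columns statistic, mean, median, hpd_lower,
#'   hpd_upper.
#' @export
biome_summary <- function(trace, mass = 0.95) {
  ret <- trace$pars[trace$pars$iteration > trace$burn_in, , drop = FALSE]
  ret$w_not_b <- 1 - ret$w_b
  stat <- c("w_u", "w_g", "w_b", "w_not_b", "delta", "beta")
  do.call(rbind, lapply(stat, function(s) {
    h <- hpd_interval(ret[[s]], mass)
    data.frame(statistic = s, mean = mean(ret[[s]]),
               median = stats::median(ret[[s]]),
               hpd_lower = h$lower, hpd_upper = h$upper)
  }))
}

#' Bayes factor for paleobiome dependence from an rj biome trace
#'
#' Indicator-count Bayes factor for `w_b > 0` (the `z = 1` model) from a
#' [biome_mcmc()] run with `rj_wb = TRUE`.
#'
#' @inheritParams biome_summary
#' @return one-row data.frame: n_nonzero, n_zero, bf, two_log_bf, band.
#' @export
biome_wb_bf <- function(trace) {
  if (!isTRUE(trace$rj_wb))
    stop("trace was not run with rj_wb = TRUE")
  ret <- trace$pars[trace$pars$iteration > trace$burn_in, , drop = FALSE]
  n1 <- sum(ret$z == 1); n0 <- sum(ret$z == 0)
  bf <- if (n0 == 0) Inf else n1 / n0
  tlb <- if (is.infinite(bf)) Inf else if (bf <= 0) -Inf else 2 * log(bf)
  data.frame(n_nonzero = n1, n_zero = n0, bf = bf, two_log_bf = tlb,
             band = classify_2logbf(max(tlb, 0)))
}

#' Model-averaged ancestral composite states
#'
#' Draws one joint node-state sample (optionally a full stochastic map)
#' per retained, thinned iteration of a [biome_mcmc()] trace, rebuilding
#' the epoch-stratified generators from that iteration's parameters, and
#' summarises node posterior probabilities with the MAP/split rule.
#'
#' @param trace a `"biome_trace"`.
#' @param tree the chronogram.
#' @param tip_states the composite-state trait matrix.
#' @param paleo the paleo-structure.
#' @param max_samples cap on the number of retained iterations used.
#' @param seed integer seed.
#' @param full_history also sample branch histories (needed for
#'   [count_biome_shifts()]).
#' @param split_pp threshold for the split rule.
#' @param root_prior as in [rate_model()] (match the MCMC run).
#' @return list with `pp`, `summary`, `n_samples` and (when
#'   `full_history`) `maps`, a list of `"stochastic_map"` objects.
#' @export
biome_ancestral <- function(trace, tree, tip_states, paleo,
                            max_samples = 500, seed = NULL,
                            full_history = FALSE, split_pp = 0.9,
                            root_prior = trace$root_prior %||% "flat") {
  ret <- trace$pars[trace$pars$iteration > trace$burn_in, , drop = FALSE]
  if (!nrow(ret)) stop("no retained samples")
  take <- unique(round(seq(1, nrow(ret),
                           length.out = min(max_samples, nrow(ret)))))
  ret <- ret[take, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  ci <- .composite_index(paleo)
  K <- nrow(paleo$epochs)
  dummy <- biome_rate_model(biome_params(1, 1, c(1, 0, 0)), paleo,
                            root_prior = root_prior)
  prep <- .ctmc_prep(tree, tip_states, dummy)
  pi <- dummy$root_prior
  k <- ci$n
  counts <- matrix(0, nrow(prep$init), k)
  maps <- if (full_history) vector("list", nrow(ret)) else NULL
  for (s in seq_len(nrow(ret))) {
    par <- biome_params(ret$delta[s], ret$beta[s],
                        c(ret$w_u[s], ret$w_g[s], ret$w_b[s]))
    Qs <- lapply(seq_len(K), function(kk)
      .composite_q_from_index(ci, par, kk))
    res <- cpp_ctmc(prep$edge, prep$nseg, prep$seg_epoch, prep$seg_dt,
                    array(unlist(Qs), dim = c(k, k, K)),
                    prep$init, prep$root, pi, 2L)
    ud <- list(prep = prep, F = res$partials, edgeP = res$edgeP, pi = pi)
    ns <- .sample_node_states(ud, 1)[, 1]
    counts[cbind(seq_len(nrow(counts)), ns)] <-
      counts[cbind(seq_len(nrow(counts)), ns)] + 1
    if (full_history) {
      model_s <- structure(list(states = composite_states(paleo),
                                Qs = lapply(Qs, function(Q) {
                                  dimnames(Q) <- list(composite_states(paleo),
                                                      composite_states(paleo))
                                  Q
                                }),
                                epoch_starts = paleo$epochs$start,
                                root_prior = pi),
                           class = "rate_model")
      maps[[s]] <- .one_map(ud, ns, model_s, TRUE, 1000, tree)
    }
  }
  pp <- counts / nrow(ret)
  colnames(pp) <- composite_states(paleo)
  out <- list(pp = pp,
              summary = .pp_summary(pp, tree, composite_states(paleo),
                                    split_pp),
              n_samples = nrow(ret))
  if (full_history) out$maps <- maps
  out
}

#' Posterior distribution of independent shifts into a biome
#'
#' For each sampled history, counts the branches on which the biome
#' component enters `target_biome` from a different biome (a branch with
#' one or more entry events counts once).  Returns the posterior count
#' distribution and per-branch shift posterior probabilities.
#'
#' @param maps list of `"stochastic_map"` objects over the composite
#'   alphabet (e.g. `biome_ancestral(..., full_history = TRUE)$maps`).
#' @param target_biome biome name (e.g. `"desert"`).
#' @return list with `counts` (per-map shift counts), `distribution`
#'   (table of counts), `mode`, and `branch_pp`.
#' @export
count_biome_shifts <- function(maps, target_biome) {
  if (inherits(maps, "stochastic_map")) maps <- list(maps)
  biome_of <- function(st) sub("^.*:", "", st)
  nedge <- nrow(maps[[1]]$edge)
  hits <- matrix(0, length(maps), nedge)
  counts <- vapply(seq_along(maps), function(i) {
    ev <- maps[[i]]$events
    if (is.null(ev) || !nrow(ev)) return(0L)
    entry <- biome_of(ev$to) == target_biome &
      biome_of(ev$from) != target_biome
    ed <- unique(ev$edge[entry])
    hits[i, ed] <<- 1
    length(ed)
  }, 0L)
  list(counts = counts,
       distribution = table(counts),
       mode = as.integer(names(which.max(table(counts)))),
       branch_pp = colMeans(hits))
}

#' @export
print.biome_trace <- function(x, ...) {
  cat(sprintf("Biome-shift MCMC trace: %d iterations, burn-in %d%s\n",
              x$iterations, x$burn_in,
              if (isTRUE(x$rj_wb)) ", rj on w_b" else ""))
  print(biome_summary(x))
  invisible(x)
}
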