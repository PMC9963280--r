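# Reversible-jump MCMC over zero/nonzero transition-rate models for a
# single discrete character on a chronogram, with indicator-based Bayes
# factors, HPD intervals, and model-averaged ancestral states.

#' Reversible-jump MCMC over transition-rate models
#'
#' Runs a Metropolis-Hastings chain over the joint space of per-transition
#' rates \eqn{q_{ij}} and binary indicators \eqn{\delta_{ij}}
#' (\eqn{\delta_{ij} = 0} fixes \eqn{q_{ij}} at zero).  Each ordered state
#' pair carries equal prior probability 1/2 on the zero and nonzero
#' models; active rates have an exponential prior whose mean defaults to
#' `10 / sum(tree$edge.length)` (ten expected events across the whole
#' tree).  Dimension jumps draw the new rate from its prior (independence
#' jump), so the acceptance ratio reduces to the likelihood ratio; rate
#' updates use a log-scale multiplier move.  Each iteration performs one
#' indicator move on a random pair and one scaling move on a random active
#' rate.
#'
#' Node states for model-averaged ancestral estimation are drawn by joint
#' conditional sampling every `thin_states` iterations.  With `chains > 1`
#' independent chains are run and pooled; a Gelman-Rubin-style potential
#' scale reduction factor on the log posterior is recorded (and reported
#' via `message()`), not enforced.
#'
#' @inheritParams prune_likelihood
#' @param iterations total iterations per chain (including burn-in).
#' @param burn_in burn-in as a fraction of `iterations` (default 0.1) or
#'   an absolute iteration count.
#' @param thin_states interval for sampling node states (0 disables).
#' @param seed integer seed.
#' @param chains number of independent chains (default 2).
#' @param rate_prior_mean mean of the exponential prior on active rates;
#'   default `10 / sum(tree$edge.length)`.
#' @param root_prior as in [rate_model()].
#' @param likelihood set `FALSE` for a prior-only run (the likelihood
#'   term is switched off; used to validate the sampler against the
#'   prior).
#' @param tune width of the log-multiplier rate move.
#' @return an object of class `"mcmc_trace"`: list with `pars` (one row
#'   per iteration per chain: iteration, chain, loglik, logpost, rate and
#'   indicator columns), `node_states` (integer matrix of sampled node
#'   states), `node_iters`, `pairs`, `states`, `burn_in`, `iterations`,
#'   `seed`, `rate_prior_mean`, `psrf`.
#' @export
rjmcmc_run <- function(tree, traits, iterations = 15000, burn_in = 0.1,
                       thin_states = 10, seed = NULL, chains = 2,
                       rate_prior_mean = NULL, root_prior = "flat",
                       likelihood = TRUE, tune = 2) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (iterations < 2) stop("'iterations' must be >= 2")
  burn <- if (burn_in < 1) floor(burn_in * iterations) else as.integer(burn_in)
  if (burn >= iterations) stop("'iterations' must exceed burn-in")
  k <- length(traits$alphabet)
  pairs <- expand.grid(from = seq_len(k), to = seq_len(k))
  pairs <- pairs[pairs$from != pairs$to, c("from", "to")]
  rownames(pairs) <- NULL
  pairs$label <- paste(traits$alphabet[pairs$from], "->",
                       traits$alphabet[pairs$to])
  np <- nrow(pairs)
  treelen <- sum(tree$edge.length)
  m_prior <- rate_prior_mean %||% (10 / treelen)

  # a dummy zero-rate model fixes the prep (single epoch, homogeneous)
  base_model <- rate_model(matrix(0, k, k, dimnames = list(traits$alphabet,
                                                           traits$alphabet)),
                           root_prior = root_prior)
  prep <- .ctmc_prep(tree, traits, base_model)
  pi <- base_model$root_prior
  qfill <- function(r) {
    Q <- matrix(0, k, k)
    Q[cbind(pairs$from, pairs$to)] <- r
    diag(Q) <- -rowSums(Q)
    Q
  }
  ll_fun <- if (likelihood) {
    function(r) .ctmc_eval(prep, list(qfill(r)), pi)$loglik
  } else function(r) 0

  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  runs <- lapply(seq_len(chains), function(cc) {
    set.seed(chain_seeds[cc])
    .rj_chain(ll_fun, qfill, np, m_prior, iterations, thin_states, tune,
              prep, pi, k)
  })
  pars <- do.call(rbind, lapply(seq_len(chains), function(cc)
    cbind(chain = cc, runs[[cc]]$pars)))
  node_states <- do.call(rbind, lapply(runs, `[[`, "node_states"))
  node_iters <- do.call(rbind, lapply(seq_len(chains), function(cc)
    data.frame(chain = rep(cc, length(runs[[cc]]$node_iters)),
               iteration = runs[[cc]]$node_iters)))
  psrf <- .psrf(lapply(runs, function(r) r$pars$logpost[-(seq_len(burn))]))
  if (chains > 1 && is.finite(psrf))
    message(sprintf("rjMCMC potential scale reduction (log posterior): %.3f",
                    psrf))
  structure(list(pars = pars, node_states = node_states,
                 node_iters = node_iters, pairs = pairs,
                 states = traits$alphabet, burn_in = burn,
                 iterations = iterations, seed = seed,
                 rate_prior_mean = m_prior, psrf = psrf,
                 trait_name = traits$name),
            class = "mcmc_trace")
}

# One rjMCMC chain.  Retries initialisation (rates redrawn from the
# prior) a bounded number of times if the likelihood is -Inf.
.rj_chain <- function(ll_fun, qfill, np, m_prior, iterations, thin_states,
                      tune, prep, pi, k) {
  delta <- rep(1L, np)
  r <- stats::rexp(np, 1 / m_prior)
  ll <- ll_fun(r * delta)
  tries <- 0
  while (!is.finite(ll) && tries < 50) {
    r <- stats::rexp(np, 1 / m_prior)
    ll <- ll_fun(r * delta)
    tries <- tries + 1
  }
  if (!is.finite(ll))
    stop("could not initialise the chain: likelihood is -Inf for 50 draws ",
         "from the rate prior")
  rates <- matrix(NA_real_, iterations, np)
  deltas <- matrix(NA_integer_, iterations, np)
  lls <- lps <- numeric(iterations)
  nst <- NULL; nit <- integer(0)
  for (it in seq_len(iterations)) {
    # indicator (birth/death) move on one random pair; prior and
    # independence-proposal terms cancel, acceptance = likelihood ratio
    p <- sample.int(np, 1)
    if (delta[p] == 1L) {
      r2 <- r; r2[p] <- 0
      ll2 <- ll_fun(r2 * replace(delta, p, 0L))
      if (log(stats::runif(1)) < ll2 - ll) {
        delta[p] <- 0L; r[p] <- 0; ll <- ll2
      }
    } else {
      rnew <- stats::rexp(1, 1 / m_prior)
      r2 <- replace(r, p, rnew)
      ll2 <- ll_fun(r2 * replace(delta, p, 1L))
      if (log(stats::runif(1)) < ll2 - ll) {
        delta[p] <- 1L; r[p] <- rnew; ll <- ll2
      }
    }
    # multiplier move on one random active rate
    act <- which(delta == 1L)
    if (length(act)) {
      p2 <- act[sample.int(length(act), 1)]
      f <- exp(tune * (stats::runif(1) - 0.5))
      r2 <- replace(r, p2, r[p2] * f)
      ll2 <- ll_fun(r2 * delta)
      la <- (ll2 - ll) +
        stats::dexp(r2[p2], 1 / m_prior, log = TRUE) -
        stats::dexp(r[p2], 1 / m_prior, log = TRUE) + log(f)
      if (log(stats::runif(1)) < la) {
        r <- r2; ll <- ll2
      }
    }
    rates[it, ] <- r * delta
    deltas[it, ] <- delta
    lls[it] <- ll
    lps[it] <- ll + sum(stats::dexp(r[delta == 1L], 1 / m_prior, log = TRUE)) +
      np * log(0.5)
    if (thin_states > 0 && it %% thin_states == 0) {
      res <- cpp_ctmc(prep$edge, prep$nseg, prep$seg_epoch, prep$seg_dt,
                      array(qfill(r * delta), dim = c(k, k, 1)),
                      prep$init, prep$root, pi, 2L)
      ud <- list(prep = prep, F = res$partials, edgeP = res$edgeP, pi = pi)
      nst <- rbind(nst, as.integer(.sample_node_states(ud, 1)))
      nit <- c(nit, it)
    }
  }
  pars <- data.frame(iteration = seq_len(iterations), loglik = lls,
                     logpost = lps)
  cn <- paste0("r_", seq_len(np))
  pars[cn] <- rates
  pars[paste0("d_", seq_len(np))] <- deltas
  list(pars = pars, node_states = nst, node_iters = nit)
}

# Gelman-Rubin-style potential scale reduction factor on a scalar summary.
.psrf <- function(chains) {
  chains <- chains[vapply(chains, length, 0L) > 1]
  if (length(chains) < 2) return(NA_real_)
  n <- min(vapply(chains, length, 0L))
  x <- vapply(chains, function(v) v[seq_len(n)], numeric(n))
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Post-burn-in rows of the parameter trace.
.retained <- function(trace) {
  trace$pars[trace$pars$iteration > trace$burn_in, , drop = FALSE]
}

#' Highest posterior density interval
#'
#' Shortest contiguous order-statistic window containing at least
#' `ceiling(mass * n)` of the samples (first such window on ties).
#'
#' @param samples numeric vector of posterior samples (at least 2).
#' @param mass interval mass (default 0.95).
#' @return list of class `"hpd_interval"` with `lower`, `upper`, `mass`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n == 0) stop("empty sample set")
  if (n < 2) stop("need at least 2 samples")
  if (!(mass > 0 && mass <= 1)) stop("'mass' must be in (0, 1]")
  s <- sort(samples)
  w <- ceiling(mass * n)
  if (w >= n) {
    i <- 1L
  } else {
    widths <- s[w:n] - s[1:(n - w + 1)]
    i <- which.min(widths)
  }
  structure(list(lower = s[i], upper = s[i + w - 1], mass = mass),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("%g%% HPD: [%.6g, %.6g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Indicator-based Bayes factor for one transition
#'
#' The Bayes factor for a nonzero transition rate is the posterior
#' probability of the nonzero model (MCMC samples visiting
#' \eqn{\delta_{ij} = 1} divided by the total) over the posterior
#' probability of the zero model; the prior ratio is 1 by construction
#' (equal prior probability on the two models) and is not included.  When
#' no retained sample visits the zero model the BF is infinite (printed
#' as `"Inf."`).  Rate summaries (mean, median, 95% HPD) are computed
#' over all retained samples, zeros included, so the HPD and the BF are
#' different summaries of the same trace and neither is derived from the
#' other.
#'
#' @param trace an `"mcmc_trace"` from [rjmcmc_run()].
#' @param from,to state labels (or indices) of the transition.
#' @param mass HPD mass (default 0.95).
#' @return one-row data.frame: transition, mean_rate, median_rate,
#'   hpd_lower, hpd_upper, n_nonzero, n_zero, bf, two_log_bf, band.
#' @export
compute_bf <- function(trace, from, to, mass = 0.95) {
  stopifnot(inherits(trace, "mcmc_trace"))
  if (is.character(from)) from <- match(from, trace$states)
  if (is.character(to)) to <- match(to, trace$states)
  idx <- which(trace$pairs$from == from & trace$pairs$to == to)
  if (length(idx) != 1) stop("unknown transition")
  ret <- .retained(trace)
  if (!nrow(ret)) stop("empty trace (no post-burn-in samples)")
  d <- ret[[paste0("d_", idx)]]
  r <- ret[[paste0("r_", idx)]]
  n1 <- sum(d == 1L); n0 <- sum(d == 0L)
  bf <- if (n0 == 0) Inf else (n1 / length(d)) / (n0 / length(d))
  tlb <- if (is.infinite(bf)) Inf else if (bf <= 0) -Inf else 2 * log(bf)
  h <- hpd_interval(r, mass)
  data.frame(transition = trace$pairs$label[idx],
             mean_rate = mean(r), median_rate = stats::median(r),
             hpd_lower = h$lower, hpd_upper = h$upper,
             n_nonzero = n1, n_zero = n0,
             bf = bf, two_log_bf = tlb,
             band = classify_2logbf(max(tlb, 0)),
             stringsAsFactors = FALSE)
}

#' Classify a 2logBF value on the Kass-Raftery bands
#'
#' `[0, 2)` is equivocal support for a nonzero transition rate, `[2, 6)`
#' strong, and `[6, Inf]` decisive.
#'
#' @param x numeric vector of 2logBF values (must be `>= 0` or infinite).
#' @return character vector of band labels.
#' @export
classify_2logbf <- function(x) {
  if (any(is.na(x))) stop("2logBF must not be NA")
  if (any(x < 0)) stop("2logBF must be >= 0 (or infinite)")
  ifelse(x < 2, "equivocal", ifelse(x < 6, "strong", "decisive"))
}

#' Format a Bayes factor for reporting
#'
#' Infinite Bayes factors print as `"Inf."`.
#'
#' @param x numeric vector of BF (or 2logBF) values.
#' @param digits significant digits.
#' @return character vector.
#' @export
format_bf <- function(x, digits = 4) {
  ifelse(is.infinite(x), "Inf.", as.character(signif(x, digits)))
}

#' Transition-rate and Bayes-factor report for every transition
#'
#' One row per ordered state pair, mirroring the usual published layout:
#' mean rate, median rate, 95% HPD interval, Bayes factor, 2logBF and the
#' Kass-Raftery band.
#'
#' @inheritParams compute_bf
#' @return data.frame of class `"bf_report"`.
#' @export
bf_report <- function(trace, mass = 0.95) {
  out <- do.call(rbind, lapply(seq_len(nrow(trace$pairs)), function(i)
    compute_bf(trace, trace$pairs$from[i], trace$pairs$to[i], mass)))
  class(out) <- c("bf_report", "data.frame")
  out
}

#' Model-averaged ancestral states from an rjMCMC trace
#'
#' Node posterior state probabilities are the frequencies of each state
#' across the node-state samples retained in the trace; because the
#' rjMCMC visits different indicator configurations, the estimate is
#' averaged over rate models.  MAP states and the `split_pp` second-state
#' rule follow [marginal_ancestral()].
#'
#' @param trace an `"mcmc_trace"` with stored node states
#'   (`thin_states > 0` in [rjmcmc_run()]).
#' @param tree the chronogram the trace was run on.
#' @param traits the trait matrix (for labels; optional).
#' @param split_pp threshold for the split rule (default 0.9).
#' @return list with `pp`, `summary` (as in [marginal_ancestral()]) and
#'   `n_samples`.
#' @export
model_averaged_ancestral <- function(trace, tree, traits = NULL,
                                     split_pp = 0.9) {
  stopifnot(inherits(trace, "mcmc_trace"))
  if (is.null(trace$node_states) || !nrow(trace$node_states))
    stop("trace holds no node-state samples; rerun with thin_states > 0")
  keep <- trace$node_iters$iteration > trace$burn_in
  ns <- trace$node_states[keep, , drop = FALSE]
  if (!nrow(ns)) stop("no retained node-state samples after burn-in")
  k <- length(trace$states)
  pp <- t(apply(ns, 2, function(col) tabulate(col, k))) / nrow(ns)
  colnames(pp) <- trace$states
  list(pp = pp,
       summary = .pp_summary(pp, tree, trace$states, split_pp),
       n_samples = nrow(ns))
}

#' Write an MCMC parameter trace as TSV
#'
#' @param trace an `"mcmc_trace"`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace$pars, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf(
    "MCMC trace: %d iterations x %d chain(s), burn-in %d, %d states\n",
    x$iterations, max(x$pars$chain), x$burn_in, length(x$states)))
  if (!is.null(x$psrf) && is.finite(x$psrf))
    cat(sprintf("  PSRF (log posterior): %.3f\n", x$psrf))
  invisible(x)
}
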