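# Correlated evolution between two binary characters: maximum-likelihood
# fits of Pagel's independent (4-rate) and dependent (8-rate) CTMC models
# on the combined 4-state space, compared by 2*(logL_dep - logL_ind).

.PAGEL_STATES <- c("00", "01", "10", "11")  # "xy": first digit x, second y

#' Pair two binary characters into a combined-state trait matrix
#'
#' Combined states are labelled `"xy"` with the first digit the state of
#' `x` and the second the state of `y` (e.g. `"10"` means x present, y
#' absent).  Both characters must be observed for every taxon.
#'
#' @param x,y `trait_matrix` objects with 2-state alphabets, or named
#'   0/1 vectors.  The second alphabet state (or value 1) codes
#'   "present".
#' @return a [trait_matrix()] on the combined alphabet
#'   `c("00","01","10","11")`, with attributes `x_name`, `y_name`,
#'   `x_alphabet`, `y_alphabet`.
#' @export
paired_binary_traits <- function(x, y) {
  bin <- function(tr, what) {
    if (inherits(tr, "trait_matrix")) {
      if (length(tr$alphabet) != 2)
        stop("'", what, "' must be binary (2-state alphabet)")
      if (any(tr$states == "?"))
        stop("'", what, "' has missing observations; both characters must ",
             "be observed for every tip")
      stats::setNames(match(tr$states, tr$alphabet) - 1L, names(tr$states))
    } else {
      v <- tr
      if (!all(v %in% c(0, 1))) stop("'", what, "' must be coded 0/1")
      stats::setNames(as.integer(v), names(v))
    }
  }
  xv <- bin(x, "x"); yv <- bin(y, "y")
  taxa <- intersect(names(xv), names(yv))
  if (!setequal(names(xv), names(yv)))
    stop("'x' and 'y' must cover the same taxa")
  comb <- paste0(xv[taxa], yv[taxa])
  tm <- trait_matrix(stats::setNames(comb, taxa), .PAGEL_STATES,
                     name = "paired_binary")
  attr(tm, "x_name") <- if (inherits(x, "trait_matrix")) x$name else "x"
  attr(tm, "y_name") <- if (inherits(y, "trait_matrix")) y$name else "y"
  attr(tm, "x_alphabet") <- if (inherits(x, "trait_matrix")) x$alphabet else c("0", "1")
  attr(tm, "y_alphabet") <- if (inherits(y, "trait_matrix")) y$alphabet else c("0", "1")
  tm
}

# Generator on the combined state space under the independent model:
# theta = (alpha_x, beta_x, alpha_y, beta_y) = gain/loss of x, gain/loss
# of y, identical whatever the other character's state.
.pagel_q_independent <- function(theta) {
  ax <- theta[1]; bx <- theta[2]; ay <- theta[3]; by <- theta[4]
  Q <- matrix(0, 4, 4, dimnames = list(.PAGEL_STATES, .PAGEL_STATES))
  Q["00", "10"] <- ax; Q["01", "11"] <- ax
  Q["10", "00"] <- bx; Q["11", "01"] <- bx
  Q["00", "01"] <- ay; Q["10", "11"] <- ay
  Q["01", "00"] <- by; Q["11", "10"] <- by
  rate_matrix(Q)
}

# Dependent model: 8 free rates, one per single-character transition in
# each context of the other character; dual transitions have rate 0.
.PAGEL_DEP_NAMES <- c("q_00_01", "q_00_10", "q_01_00", "q_01_11",
                      "q_10_00", "q_10_11", "q_11_01", "q_11_10")
.pagel_q_dependent <- function(theta) {
  Q <- matrix(0, 4, 4, dimnames = list(.PAGEL_STATES, .PAGEL_STATES))
  Q["00", "01"] <- theta[1]; Q["00", "10"] <- theta[2]
  Q["01", "00"] <- theta[3]; Q["01", "11"] <- theta[4]
  Q["10", "00"] <- theta[5]; Q["10", "11"] <- theta[6]
  Q["11", "01"] <- theta[7]; Q["11", "10"] <- theta[8]
  rate_matrix(Q)
}

.pagel_fingerprint <- function(tree, traits) {
  paste(c(tree$tip.label, traits$states[tree$tip.label]), collapse = "|")
}

# Shared multistart bounded quasi-Newton ML fit on log-rates.
.pagel_fit <- function(tree, traits, qbuild, npar, par_names, kind,
                       n_starts, seed, root_prior, lower, upper) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (!identical(traits$alphabet, .PAGEL_STATES))
    stop("'traits' must be a paired_binary_traits() object")
  base <- rate_model(qbuild(rep(1e-3, npar)), root_prior = root_prior)
  prep <- .ctmc_prep(tree, traits, base)
  pi <- base$root_prior
  negll <- function(lr) {
    ll <- .ctmc_eval(prep, list(qbuild(exp(lr))), pi)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  treelen <- sum(tree$edge.length)
  set.seed(seed)
  starts <- rbind(rep(log(2 / treelen), npar),
                  matrix(stats::runif((n_starts - 1) * npar, -7, 0),
                         ncol = npar))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("likelihood non-finite for every start; cannot fit ", kind, " model")
  structure(list(model = kind,
                 rates = stats::setNames(exp(best$par), par_names),
                 loglik = -best$value,
                 convergence = best$convergence,
                 n_starts = n_starts,
                 root_prior = root_prior,
                 Q = qbuild(exp(best$par)),
                 fingerprint = .pagel_fingerprint(tree, traits)),
            class = "pagel_fit")
}

#' Fit the independent model of two binary characters
#'
#' Four free rates (gain and loss of each character, unaffected by the
#' state of the other) fitted by multistart bounded quasi-Newton
#' maximisation of the pruning log-likelihood on the combined 4-state
#' space.  Because the combined generator is a direct sum, the
#' independent-model likelihood factorises into the product of the two
#' single-character likelihoods.
#'
#' @param tree a chronogram (or rooted `phylo`; the model is
#'   time-homogeneous).
#' @param traits a [paired_binary_traits()] trait matrix.
#' @param n_starts number of optimiser starts (default 10).
#' @param seed seed for the multistart draws.
#' @param root_prior as in [rate_model()].
#' @param lower,upper bounds on log-rates.
#' @return an object of class `"pagel_fit"`.
#' @export
fit_independent <- function(tree, traits, n_starts = 10, seed = 1,
                            root_prior = "flat", lower = -12, upper = 3) {
  .pagel_fit(tree, traits, .pagel_q_independent, 4,
             c("alpha_x", "beta_x", "alpha_y", "beta_y"), "independent",
             n_starts, seed, root_prior, lower, upper)
}

#' Fit the dependent model of two binary characters
#'
#' Eight free rates: each single-character transition has its own rate in
#' each context of the other character; transitions changing both
#' characters at once are disallowed (rate 0).  The independent model is
#' nested inside this one.
#'
#' @inheritParams fit_independent
#' @return an object of class `"pagel_fit"`.
#' @export
fit_dependent <- function(tree, traits, n_starts = 10, seed = 1,
                          root_prior = "flat", lower = -12, upper = 3) {
  .pagel_fit(tree, traits, .pagel_q_dependent, 8, .PAGEL_DEP_NAMES,
             "dependent", n_starts, seed, root_prior, lower, upper)
}

#' Compare dependent and independent fits
#'
#' Reports both log-likelihoods and the statistic
#' \eqn{2(\log L_{dep} - \log L_{ind})}, which is non-negative at the
#' optimum by nesting.  The statistic is read on the same
#' interpretation bands as [classify_2logbf()] (a value above 6 is
#' decisive evidence for dependence); the chi-squared (4 df) tail
#' probability is also reported as a frequentist reference.
#'
#' @param fit_ind an independent [fit_independent()] fit.
#' @param fit_dep a dependent [fit_dependent()] fit on the same data.
#' @return object of class `"pagel_comparison"`: list with `loglik_ind`,
#'   `loglik_dep`, `statistic`, `band`, `p_chisq`, `df`.
#' @export
compare_models <- function(fit_ind, fit_dep) {
  stopifnot(inherits(fit_ind, "pagel_fit"), inherits(fit_dep, "pagel_fit"))
  if (fit_ind$model != "independent" || fit_dep$model != "dependent")
    stop("arguments must be an independent fit and a dependent fit")
  if (!identical(fit_ind$fingerprint, fit_dep$fingerprint))
    stop("fits were computed on different data")
  stat <- 2 * (fit_dep$loglik - fit_ind$loglik)
  if (stat < -1e-6)
    warning("dependent optimum below independent optimum; optimizer did ",
            "not converge")
  stat_c <- max(stat, 0)
  structure(list(loglik_ind = fit_ind$loglik, loglik_dep = fit_dep$loglik,
                 statistic = stat, band = classify_2logbf(stat_c),
                 p_chisq = stats::pchisq(stat_c, df = 4, lower.tail = FALSE),
                 df = 4),
            class = "pagel_comparison")
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat(sprintf("Pagel %s model fit: logL = %.6f\n", x$model, x$loglik))
  print(signif(x$rates, 4))
  invisible(x)
}

#' @export
print.pagel_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "Correlated-evolution test\n",
    "  logL (independent): %.6f\n",
    "  logL (dependent):   %.6f\n",
    "  2*(dlogL) = %.6f  [%s; chi^2_4 p = %.4g]\n"),
    x$loglik_ind, x$loglik_dep, x$statistic, x$band, x$p_chisq))
  invisible(x)
}
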