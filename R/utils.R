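`%||%` <- function(a, b) if (is.null(a)) b else a

# Dirichlet draw / log-density (small helpers; no installed package owns
# these for plain numeric vectors).
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

.ddirichlet_log <- function(x, alpha) {
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Monte Carlo standard error by batch means
#'
#' Standard error of the mean of a (possibly autocorrelated) MCMC sample,
#' estimated from the variance of contiguous batch means.
#'
#' @param x numeric vector of samples.
#' @param batches number of contiguous batches (default 20).
#' @return the batch-means standard error of `mean(x)`.
#' @export
mcse_batch <- function(x, batches = 20) {
  n <- length(x)
  if (n < 2 * batches) batches <- max(2, floor(n / 2))
  size <- floor(n / batches)
  m <- vapply(seq_len(batches), function(b)
    mean(x[((b - 1) * size + 1):(b * size)]), 0)
  stats::sd(m) / sqrt(batches)
}
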