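make_toy_trace <- function(n1, n0, rates = NULL) {
  # minimal 2-state trace with controlled indicator counts for pair 1
  N <- n1 + n0
  pars <- data.frame(chain = 1, iteration = seq_len(N),
                     loglik = 0, logpost = 0,
                     r_1 = rates %||% c(rexp(n1, 10), rep(0, n0)),
                     r_2 = 0,
                     d_1 = c(rep(1L, n1), rep(0L, n0)),
                     d_2 = 0L)
  structure(list(pars = pars, node_states = NULL,
                 node_iters = data.frame(chain = integer(0),
                                         iteration = integer(0)),
                 pairs = data.frame(from = c(1L, 2L), to = c(2L, 1L),
                                    label = c("a -> b", "b -> a")),
                 states = c("a", "b"), burn_in = 0L, iterations = N,
                 seed = NULL, rate_prior_mean = 0.1, psrf = NA_real_),
            class = "mcmc_trace")
}

test_that("the Bayes factor is exact hand arithmetic on indicator counts", {
  set.seed(1)
  bf <- compute_bf(make_toy_trace(6750, 6750), "a", "b")
  expect_equal(bf$bf, 1)
  expect_equal(bf$two_log_bf, 0)
  expect_equal(bf$band, "equivocal")
  bf <- compute_bf(make_toy_trace(12150, 1350), "a", "b")
  expect_equal(bf$bf, 9)
  expect_equal(bf$two_log_bf, 2 * log(9), tolerance = 1e-12)
  expect_equal(bf$band, "strong")
  bf <- compute_bf(make_toy_trace(13500, 0), "a", "b")
  expect_true(is.infinite(bf$bf))
  expect_equal(bf$band, "decisive")
  expect_equal(format_bf(bf$bf), "Inf.")
})

test_that("2logBF bands follow the Kass-Raftery mapping", {
  expect_equal(classify_2logbf(7.78), "decisive")
  expect_equal(classify_2logbf(5.974), "strong")
  expect_equal(classify_2logbf(0.248), "equivocal")
  expect_equal(classify_2logbf(c(0, 1.99, 2, 5.99, 6, Inf)),
               c("equivocal", "equivocal", "strong", "strong",
                 "decisive", "decisive"))
  expect_error(classify_2logbf(-0.1), ">= 0")
})

test_that("HPD intervals are the shortest order-statistic windows", {
  h <- hpd_interval(rep(3.2, 10))
  expect_equal(h$lower, 3.2)
  expect_equal(h$upper, 3.2)
  # uniform grid 0..99, mass 0.95: any window of 95 works; brute force
  x <- 0:99
  h <- hpd_interval(x, 0.95)
  w <- 95
  widths <- sapply(1:(100 - w + 1), function(i) x[i + w - 1] - x[i])
  expect_equal(h$upper - h$lower, min(widths))
  # point mass at zero plus a few positive values: [0, u] shape
  set.seed(2)
  x <- c(rep(0, 80), rexp(20, 100))
  h <- hpd_interval(x, 0.95)
  expect_equal(h$lower, 0)
  expect_gt(h$upper, 0)
  # random samples: brute-force minimal-window search agrees
  for (i in 1:10) {
    x <- rnorm(57)
    h <- hpd_interval(x, 0.9)
    s <- sort(x)
    w <- ceiling(0.9 * length(x))
    widths <- s[w:length(s)] - s[1:(length(s) - w + 1)]
    expect_equal(h$upper - h$lower, min(widths), tolerance = 1e-12)
  }
  expect_error(hpd_interval(numeric(0)), "empty")
  expect_error(hpd_interval(1), "at least 2")
})

test_that("chains restarted with the same seed give identical traces", {
  set.seed(31)
  tr <- rand_chrono(12, root = 5)
  tm <- rand_tips(tr, c("a", "b"))
  t1 <- rjmcmc_run(tr, tm, iterations = 200, seed = 99, chains = 1,
                   thin_states = 20)
  t2 <- rjmcmc_run(tr, tm, iterations = 200, seed = 99, chains = 1,
                   thin_states = 20)
  expect_identical(t1$pars, t2$pars)
  expect_identical(t1$node_states, t2$node_states)
})

test_that("zero-indicator samples record exactly zero rates", {
  set.seed(37)
  tr <- rand_chrono(15, root = 5)
  tm <- rand_tips(tr, c("a", "b"))
  tt <- rjmcmc_run(tr, tm, iterations = 400, seed = 5, chains = 1,
                   thin_states = 0)
  for (j in 1:2) {
    r <- tt$pars[[paste0("r_", j)]]
    d <- tt$pars[[paste0("d_", j)]]
    expect_true(all(r[d == 0L] == 0))
    expect_true(all(r[d == 1L] > 0))
  }
})

test_that("a prior-only run recovers the equal indicator prior and the rate prior", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  tm <- trait_matrix(c(A = "a", B = "b", C = "a"), c("a", "b"))
  tt <- rjmcmc_run(tr, tm, iterations = 6000, seed = 17, chains = 1,
                   likelihood = FALSE, thin_states = 0,
                   rate_prior_mean = 0.2)
  for (j in 1:2) {
    d <- tt$pars[[paste0("d_", j)]][tt$pars$iteration > tt$burn_in]
    # prior-only indicator flips are antithetic, so the iid binomial SE
    # is a conservative Monte Carlo SE for the proportion
    se <- max(mcse_batch(d), sqrt(0.25 / length(d)))
    expect_lt(abs(mean(d) - 0.5), 3 * se)
    r <- tt$pars[[paste0("r_", j)]][tt$pars$iteration > tt$burn_in]
    r <- r[r > 0]
    expect_lt(abs(mean(r) - 0.2), 3 * mcse_batch(r))
  }
})

test_that("model-averaged ancestral states agree with fixed-rate marginals", {
  # With the indicator space pinned (every rate strongly supported) and a
  # sharp prior, the model-averaged node PPs converge to the marginal
  # ancestral PPs under the generating model.
  set.seed(41)
  tr <- rand_chrono(5, root = 3)
  q <- 0.5
  m <- rate_model(rate_matrix(matrix(c(0, q, q, 0), 2, 2), c("a", "b")))
  tm <- rand_tips(tr, c("a", "b"))
  nmaps <- 4000
  maps <- stochastic_map(tr, tm, m, seed = 43, nmaps = nmaps,
                         full_history = FALSE)
  freq <- Reduce(`+`, lapply(maps, function(sm)
    outer(sm$node_states, c("a", "b"), `==`) + 0)) / nmaps
  want <- marginal_ancestral(tr, tm, m)$pp
  for (i in seq_len(nrow(want))) {
    p <- want[i, 1]
    se <- max(sqrt(p * (1 - p) / nmaps), 1e-4)
    expect_lt(abs(freq[i, 1] - p), 4 * se)
  }
  # degenerate one-sample trace: PP concentrates on that draw
  tt <- rjmcmc_run(tr, tm, iterations = 20, burn_in = 10, seed = 3,
                   chains = 1, thin_states = 20)
  ma <- model_averaged_ancestral(tt, tr)
  expect_equal(ma$n_samples, 1)
  expect_true(all(ma$pp %in% c(0, 1)))
})

test_that("rjMCMC finds the nonzero rate and stays agnostic on the zero rate", {
  tr <- simulate_chronogram(120, root_age = 15.8, seed = 51)
  Q <- rate_matrix(matrix(c(0, 0.05, 0, 0), 2, 2, byrow = TRUE),
                   c("a", "b"))
  truth <- simulate_character(tr, rate_model(Q, root_prior = c(1, 0)),
                              seed = 52)
  tt <- rjmcmc_run(tr, truth$tip_states, iterations = 2500, seed = 53,
                   chains = 1, thin_states = 0)
  ab <- compute_bf(tt, "a", "b")
  ba <- compute_bf(tt, "b", "a")
  expect_gte(ab$two_log_bf, 2)          # the true signal is detected
  expect_lt(ba$two_log_bf, ab$two_log_bf)
  # report covers every ordered pair and is internally consistent
  rep <- bf_report(tt)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$hpd_lower <= rep$median_rate + 1e-12))
  expect_true(all(rep$median_rate <= rep$hpd_upper + 1e-12))
})
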