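test_that("pairing two binary characters builds the combined alphabet", {
  x <- trait_matrix(c(A = "caudex_absent", B = "caudex_present"),
                    c("caudex_absent", "caudex_present"))
  y <- trait_matrix(c(A = "habitat_generalist", B = "bare_rock_specialist"),
                    c("habitat_generalist", "bare_rock_specialist"))
  xy <- paired_binary_traits(x, y)
  expect_equal(xy$alphabet, c("00", "01", "10", "11"))
  expect_equal(unname(xy$states[c("A", "B")]), c("00", "11"))
  expect_error(paired_binary_traits(x, trait_matrix(
    c(A = "g"), c("g", "r"))), "same taxa")
})

test_that("the independent likelihood factorises over the two characters", {
  set.seed(3)
  tr <- rand_chrono(20, root = 5)
  ax <- 0.3; bx <- 0.2; ay <- 0.15; by <- 0.4
  Qx <- rate_matrix(matrix(c(0, ax, bx, 0), 2, 2, byrow = TRUE), c("0", "1"))
  Qy <- rate_matrix(matrix(c(0, ay, by, 0), 2, 2, byrow = TRUE), c("0", "1"))
  xs <- rand_tips(tr, c("0", "1"))
  ys <- rand_tips(tr, c("0", "1"))
  xy <- paired_binary_traits(xs, ys)
  Qc <- perishift:::.pagel_q_independent(c(ax, bx, ay, by))
  llc <- prune_likelihood(tr, xy, rate_model(Qc))$loglik
  llx <- prune_likelihood(tr, xs, rate_model(Qx))$loglik
  lly <- prune_likelihood(tr, ys, rate_model(Qy))$loglik
  expect_equal(llc, llx + lly, tolerance = 1e-8)
})

test_that("the dependent likelihood matches the enumeration oracle", {
  set.seed(5)
  tr <- rand_chrono(3, root = 2)
  xy <- trait_matrix(setNames(c("00", "11", "10"), tr$tip.label),
                     c("00", "01", "10", "11"))
  th <- runif(8, 0.05, 0.6)
  Q <- perishift:::.pagel_q_dependent(th)
  m <- rate_model(Q)
  expect_equal(prune_likelihood(tr, xy, m)$loglik,
               oracle_loglik(tr, xy$states, m$states, list(Q), NULL,
                             m$root_prior),
               tolerance = 1e-10)
  # dual transitions are structurally disallowed
  expect_equal(Q["00", "11"], 0)
  expect_equal(Q["01", "10"], 0)
  expect_equal(Q["10", "01"], 0)
  expect_equal(Q["11", "00"], 0)
})

test_that("monomorphic data are handled at the rate boundaries", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  xy <- trait_matrix(c(A = "10", B = "10", C = "10"),
                     c("00", "01", "10", "11"))
  # with all rates at zero the likelihood is the root-prior mass of the
  # observed combined state
  tiny <- perishift:::.pagel_q_independent(rep(1e-12, 4))
  expect_equal(prune_likelihood(tr, xy, rate_model(tiny))$loglik,
               log(0.25), tolerance = 1e-9)
  # the ML fit can only improve on that (absorbing dynamics toward the
  # observed state raise the likelihood above the flat root mass)
  fit <- fit_independent(tr, xy, n_starts = 3, seed = 1)
  expect_gte(fit$loglik, log(0.25) - 1e-6)
  expect_lte(fit$loglik, 0)
})

test_that("constraining the dependent model reproduces the independent fit", {
  set.seed(7)
  tr <- rand_chrono(15, root = 5)
  xy <- rand_tips(tr, c("00", "01", "10", "11"))
  th <- c(0.2, 0.3, 0.1, 0.25)
  Qi <- perishift:::.pagel_q_independent(th)
  # dependent parameterisation tied to the independent rates
  Qd <- perishift:::.pagel_q_dependent(c(
    th[3],  # 00->01: y gain
    th[1],  # 00->10: x gain
    th[4],  # 01->00: y loss
    th[1],  # 01->11: x gain
    th[2],  # 10->00: x loss
    th[3],  # 10->11: y gain
    th[2],  # 11->01: x loss
    th[4])) # 11->10: y loss
  expect_equal(Qd, Qi)
  m <- rate_model(Qi)
  expect_equal(prune_likelihood(tr, xy, rate_model(Qd))$loglik,
               prune_likelihood(tr, xy, m)$loglik)
})

test_that("model comparison reports the doubled log-likelihood difference", {
  f1 <- structure(list(model = "independent", loglik = -65.153536,
                       fingerprint = "f"), class = "pagel_fit")
  f2 <- structure(list(model = "dependent", loglik = -51.090204,
                       fingerprint = "f"), class = "pagel_fit")
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$statistic, 28.126664, tolerance = 1e-9)
  expect_equal(cmp$band, "decisive")
  # identical fits: statistic 0, equivocal
  cmp0 <- compare_models(
    structure(list(model = "independent", loglik = -10, fingerprint = "f"),
              class = "pagel_fit"),
    structure(list(model = "dependent", loglik = -10, fingerprint = "f"),
              class = "pagel_fit"))
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$band, "equivocal")
  # mismatched data are refused
  f3 <- structure(list(model = "dependent", loglik = -5, fingerprint = "g"),
                  class = "pagel_fit")
  expect_error(compare_models(f1, f3), "different data")
})

test_that("dependence simulated into the data raises the statistic", {
  set.seed(11)
  tr <- simulate_chronogram(100, root_age = 15.8, seed = 12)
  # y gains only when x = 1
  Qdep <- perishift:::.pagel_q_dependent(
    c(0, 0.08, 0.3, 0.08, 0.08, 0.3, 0.08, 0.005))
  truth <- simulate_character(tr, rate_model(Qdep, root_prior = c(1, 0, 0, 0)))
  fi <- fit_independent(tr, truth$tip_states, n_starts = 4, seed = 1)
  fd <- fit_dependent(tr, truth$tip_states, n_starts = 4, seed = 1)
  cmp <- compare_models(fi, fd)
  expect_gte(cmp$statistic, -1e-6)      # nesting
  expect_gt(cmp$statistic, qchisq(0.95, 4))
})

test_that("the maximum-likelihood surface agrees with an independent fitter", {
  skip_if_not_installed("phytools")
  set.seed(13)
  tr <- rand_chrono(25, root = 8)
  mx <- rate_model(rate_matrix(matrix(c(0, .15, .2, 0), 2, 2, byrow = TRUE),
                               c("0", "1")))
  x <- simulate_character(tr, mx)$tip_states
  y <- simulate_character(tr, mx)$tip_states
  xv <- setNames(factor(x$states), names(x$states))
  yv <- setNames(factor(y$states), names(y$states))
  ref <- phytools::fitPagel(ape::as.phylo(tr), xv, yv, pi = "equal")
  xy <- paired_binary_traits(x, y)
  fi <- fit_independent(tr, xy, n_starts = 8, seed = 2)
  fd <- fit_dependent(tr, xy, n_starts = 8, seed = 2)
  expect_equal(as.numeric(fi$loglik), as.numeric(ref$independent.logL),
               tolerance = 1e-3)
  # a multistart optimum must be at least as good as the reference's
  expect_gte(fd$loglik, as.numeric(ref$dependent.logL) - 1e-3)
  expect_lte(fd$loglik, 0)
})
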