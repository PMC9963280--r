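test_that("composite generators implement the three-graph mixture", {
  paleo <- paleo_perityleae()
  cs <- composite_states(paleo)
  # graph-free model: all dispersal rates delta*w_u, all shifts beta*w_u
  p0 <- biome_params(0.05, 0.08, c(1, 0, 0))
  for (k in 1:4) {
    Q <- build_composite_q(p0, paleo, k)
    off <- Q[row(Q) != col(Q)]
    expect_true(all(abs(off[off > 0] - c(0.05, 0.08)) < 1e-12 |
                      abs(off[off > 0] - 0.05) < 1e-12 |
                      abs(off[off > 0] - 0.08) < 1e-12))
    disp <- Q["TransMexVolcanicBelt:tropical", "BajaCalifornia:tropical"]
    expect_equal(disp, 0.05)
    shift <- Q["TransMexVolcanicBelt:tropical", "TransMexVolcanicBelt:desert"]
    expect_equal(shift, 0.08)
    expect_true(max(abs(rowSums(Q))) < 1e-12)
  }
  # pure paleogeography: no dispersal into South America, ever
  pg <- biome_params(0.05, 0.08, c(0, 1, 0))
  for (k in 1:4) {
    Q <- build_composite_q(pg, paleo, k)
    into_sa <- grepl("^SouthAmerica:", cs)
    expect_true(all(Q[!into_sa, into_sa] == 0))
  }
  # desert-shift availability contrast between epochs
  pb <- biome_params(0.05, 0.08, c(0.2, 0.3, 0.5))
  Qrec <- build_composite_q(pb, paleo, 4)
  Qearly <- build_composite_q(pb, paleo, 2)
  from <- "BasinAndRange:subtropical"; to <- "BasinAndRange:desert"
  expect_equal(Qrec[from, to], 0.08 * (0.2 + 0.3 + 0.5 * 1))
  expect_equal(Qearly[from, to], 0.08 * (0.2 + 0.3 + 0.5 * 0))
  # simultaneous area+biome change is disallowed
  expect_equal(Qrec["BajaCalifornia:tropical", "BasinAndRange:desert"], 0)
  expect_error(build_composite_q(pb, paleo, 5), "invalid epoch")
})

test_that("composite generators are valid CTMC generators (property)", {
  set.seed(3)
  paleo <- paleo_perityleae()
  for (i in 1:10) {
    p <- biome_params(runif(1, .01, .2), runif(1, .01, .2),
                      perishift:::.rdirichlet(c(1, 1, 1)))
    for (k in 1:4) {
      Q <- build_composite_q(p, paleo, k)
      expect_true(max(abs(rowSums(Q))) < 1e-12)
      expect_true(all(Q[row(Q) != col(Q)] >= 0))
    }
  }
})

test_that("w_b = 0 makes the likelihood invariant to paleobiome matrices", {
  set.seed(5)
  paleo <- paleo_perityleae()
  tr <- simulate_chronogram(20, root_age = 15.8, seed = 6)
  tips <- rand_tips(tr, composite_states(paleo))
  p <- biome_params(0.05, 0.08, c(0.6, 0.4, 0))
  ll1 <- prune_likelihood(tr, tips, biome_rate_model(p, paleo))$loglik
  # perturb every availability matrix
  paleo2 <- paleo
  for (k in 1:4) {
    B <- paleo$biome_availability[[k]]
    B[] <- sample(c(0, 0.1, 1), length(B), replace = TRUE)
    paleo2$biome_availability[[k]] <- B
  }
  ll2 <- prune_likelihood(tr, tips, biome_rate_model(p, paleo2))$loglik
  expect_equal(ll1, ll2, tolerance = 1e-12)
  # and with w_b > 0 the same perturbation changes the likelihood
  p3 <- biome_params(0.05, 0.08, c(0.4, 0.3, 0.3))
  ll3 <- prune_likelihood(tr, tips, biome_rate_model(p3, paleo))$loglik
  ll4 <- prune_likelihood(tr, tips, biome_rate_model(p3, paleo2))$loglik
  expect_gt(abs(ll3 - ll4), 1e-6)
})

test_that("all-ones adjacency collapses to a time-homogeneous model", {
  set.seed(7)
  areas <- c("A1", "A2"); biomes <- c("b1", "b2")
  ones <- list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2))
  ps <- paleo_structure(
    data.frame(name = c("e1", "e2", "e3"), start = c(30, 20, 10),
               end = c(20, 10, 0)),
    areas, biomes, ones, ones)
  ps1 <- paleo_structure(data.frame(name = "all", start = 30, end = 0),
                         areas, biomes, list(matrix(1, 2, 2)),
                         list(matrix(1, 2, 2)))
  p <- biome_params(0.07, 0.11, c(0.2, 0.5, 0.3))
  tr <- simulate_chronogram(15, root_age = 25, seed = 8)
  tips <- rand_tips(tr, composite_states(ps))
  ll_strat <- prune_likelihood(tr, tips, biome_rate_model(p, ps))$loglik
  ll_homog <- prune_likelihood(tr, tips, biome_rate_model(p, ps1))$loglik
  expect_equal(ll_strat, ll_homog, tolerance = 1e-12)
})

test_that("zero adjacency does not forbid dispersal when w_u > 0", {
  # long-distance dispersal into the isolated area stays representable
  paleo <- paleo_perityleae()
  p <- biome_params(0.05, 0.08, c(0.3, 0.6, 0.1))
  for (k in 1:4) {
    Q <- build_composite_q(p, paleo, k)
    P <- transition_probs(Q, 5)
    sa <- grepl("^SouthAmerica:", composite_states(paleo))
    expect_true(all(P[!sa, "SouthAmerica:tropical"] > 0))
  }
})

test_that("the weight simplex holds at every retained iteration", {
  set.seed(9)
  paleo <- paleo_perityleae()
  tr <- simulate_chronogram(15, root_age = 15.8, seed = 10)
  bp <- biome_params(0.05, 0.08, c(0.3, 0.25, 0.45))
  tips <- simulate_character(tr, biome_rate_model(bp, paleo),
                             seed = 11)$tip_states
  tt <- biome_mcmc(tr, tips, paleo, iterations = 400, seed = 12)
  w <- tt$pars[, c("w_u", "w_g", "w_b")]
  expect_true(all(abs(rowSums(w) - 1) < 1e-9))
  expect_true(all(w >= 0))
  s <- biome_summary(tt)
  expect_equal(s$statistic[1:4], c("w_u", "w_g", "w_b", "w_not_b"))
  expect_equal(s$mean[s$statistic == "w_not_b"],
               1 - s$mean[s$statistic == "w_b"], tolerance = 1e-12)
})

test_that("a prior-only run recovers flat Dirichlet weight moments", {
  paleo <- paleo_perityleae()
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  tips <- trait_matrix(
    setNames(rep("BasinAndRange:desert", 3), tr$tip.label),
    composite_states(paleo))
  tt <- biome_mcmc(tr, tips, paleo, iterations = 8000, seed = 13,
                   likelihood = FALSE)
  ret <- tt$pars[tt$pars$iteration > tt$burn_in, ]
  # Dirichlet(1,1,1): mean 1/3, sd sqrt(1/18)
  for (col in c("w_u", "w_g", "w_b")) {
    se <- mcse_batch(ret[[col]])
    expect_lt(abs(mean(ret[[col]]) - 1 / 3), 3 * se)
    expect_lt(abs(sd(ret[[col]]) - sqrt(1 / 18)), 0.03)
  }
  # and the rj indicator sits at its equal prior odds
  trj <- biome_mcmc(tr, tips, paleo, iterations = 8000, seed = 14,
                    likelihood = FALSE, rj_wb = TRUE)
  retj <- trj$pars[trj$pars$iteration > trj$burn_in, ]
  se <- mcse_batch(retj$z)
  expect_lt(abs(mean(retj$z) - 0.5), 3 * se)
  expect_true(all(retj$w_b[retj$z == 0] == 0))
  bf <- biome_wb_bf(trj)
  expect_true(bf$band %in% c("equivocal"))
})

test_that("ancestral composite states agree with enumeration marginals", {
  set.seed(15)
  areas <- c("A1", "A2"); biomes <- c("b1", "b2")
  ps <- paleo_structure(
    data.frame(name = c("old", "new"), start = c(10, 2), end = c(2, 0)),
    areas, biomes,
    list(matrix(1, 2, 2), matrix(c(1, 0.1, 0.1, 1), 2, 2)),
    list(matrix(1, 2, 2), matrix(c(1, 1, 0.1, 1), 2, 2, byrow = TRUE)))
  p <- biome_params(0.2, 0.3, c(0.3, 0.3, 0.4))
  model <- biome_rate_model(p, ps)
  tr <- rand_chrono(4, root = 5)
  tips <- rand_tips(tr, composite_states(ps))
  # fixed-parameter trace: every retained row holds the same parameters
  fake <- structure(list(
    pars = data.frame(iteration = 1:400, loglik = 0, logpost = 0,
                      delta = 0.2, beta = 0.3, w_u = 0.3, w_g = 0.3,
                      w_b = 0.4, z = 1),
    paleo = ps, burn_in = 0L, iterations = 400L, seed = 1,
    rj_wb = FALSE, root_prior = "flat"), class = "biome_trace")
  anc <- biome_ancestral(fake, tr, tips, ps, max_samples = 400, seed = 16)
  want <- oracle_marginals(tr, tips$states, model$states, model$Qs,
                           ps$epochs$start, model$root_prior)
  for (i in seq_len(nrow(want))) for (s in seq_len(ncol(want))) {
    se <- max(sqrt(want[i, s] * (1 - want[i, s]) / 400), 5e-3)
    expect_lt(abs(anc$pp[i, s] - want[i, s]), 4 * se)
  }
})

test_that("desert-shift counting tallies branches with entry events", {
  paleo <- paleo_perityleae()
  cs <- composite_states(paleo)
  edge <- matrix(c(5, 5, 6, 6, 6, 1, 2, 3, 4, 5), ncol = 2)
  mk <- function(events) structure(
    list(node_states = setNames(rep("BasinAndRange:subtropical", 6),
                                c("t1", "t2", "t3", "t4", "n5", "n6")),
         events = events, edge = edge, states = cs),
    class = "stochastic_map")
  none <- mk(data.frame(edge = integer(0), age = numeric(0),
                        from = character(0), to = character(0)))
  two <- mk(data.frame(
    edge = c(1, 3),
    age = c(2, 1),
    from = c("BasinAndRange:subtropical", "BasinAndRange:tropical"),
    to = c("BasinAndRange:desert", "BasinAndRange:desert")))
  # a desert-to-desert dispersal is not an entry; a double entry on one
  # branch still counts once
  tricky <- mk(data.frame(
    edge = c(1, 1, 2),
    age = c(3, 1, 2),
    from = c("BasinAndRange:subtropical", "BasinAndRange:subtropical",
             "BasinAndRange:desert"),
    to = c("BasinAndRange:desert", "BasinAndRange:desert",
           "BajaCalifornia:desert")))
  out <- count_biome_shifts(list(none, two, tricky), "desert")
  expect_equal(out$counts, c(0L, 2L, 1L))
  expect_equal(out$branch_pp[1], 2 / 3)
  expect_equal(out$branch_pp[3], 1 / 3)
  expect_equal(out$branch_pp[2], 0)
})
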