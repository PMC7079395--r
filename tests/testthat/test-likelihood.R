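test_that("branch_partial applies the closed-form interval transitions", {
  w <- partial_lik(c(0, 0, 1)) # child observed in state m
  # zero-length branch with no events: unchanged
  out <- branch_partial(w, 0, 1, c(0.2, 0.3, 0.5))
  expect_equal(out$w, c(0, 0, 1))
  # single interval: omega_0(u) = P_{um}
  out <- branch_partial(w, 0.5, 1, c(0.2, 0.3, 0.5))
  expect_equal(out$w[1] * exp(out$log_scale), (1 - exp(-0.5)) * 0.5)
  # one event mid-branch equals the enumeration oracle
  set.seed(21)
  pi0 <- drop(rdirichlet3(1)); pi1 <- drop(rdirichlet3(1))
  ev <- data.frame(branch = 2L, pos = 0.35, pi_u = pi1[1], pi_p = pi1[2],
                   pi_m = pi1[3])
  out <- branch_partial(w, 0.7, 1.3, pi0, ev)
  A <- oracle_branch_matrix(0.7, 1.3, pi0, ev)
  expect_equal(out$w * exp(out$log_scale), drop(A %*% c(0, 0, 1)),
               tolerance = 1e-9)
  expect_error(branch_partial(w, 0.2, 1, pi0, ev), "inside")
})

test_that("node_partial builds indicators, products and observation masks", {
  expect_equal(node_partial(list(), "p")$w, c(0, 1, 0))
  expect_equal(node_partial(list(), NA)$w, c(1, 1, 1)) # missing tip
  a <- partial_lik(c(0.3, 0.2, 0.1)); b <- partial_lik(c(0.5, 0.4, 0.9))
  out <- node_partial(list(a, b), "u")
  expect_equal(out$w * exp(out$log_scale), c(0.3 * 0.5, 0, 0))
  out2 <- node_partial(list(a, b))
  expect_equal(out2$w * exp(out2$log_scale), c(0.15, 0.08, 0.09))
  expect_error(node_partial(list()), "observation")
})

test_that("site likelihood matches hand evaluation on a single branch", {
  tr <- two_node_tree(l = 1)
  cfg <- iwe_config(c(0.2, 0.3, 0.5))
  # root u, tip m, no invariant sites, alpha so large all rates are 1
  theta <- global_params(r = 0, alpha = 1e8, mu = 0)
  ll <- site_log_likelihood(c(1, 3), tr, cfg, theta)
  expect_equal(ll, log(0.2 * (1 - exp(-1)) * 0.5), tolerance = 1e-5)
  # fully invariant sites: identical states give the root frequency ...
  theta1 <- global_params(r = 1, alpha = 1, mu = 0)
  expect_equal(site_log_likelihood(c(2, 2), tr, cfg, theta1), log(0.3))
  # ... and differing states are impossible
  expect_warning(
    ll0 <- site_log_likelihood(c(1, 2), tr, cfg, theta1), "zero likelihood")
  expect_identical(ll0, -Inf)
})

test_that("island and tree likelihoods add over sites and islands", {
  tr <- cherry_tree()
  cfg <- iwe_config(c(0.3, 0.3, 0.4))
  theta <- global_params(r = 0.2, alpha = 1.3, mu = 0.5)
  s1 <- site_log_likelihood(c(1, 2, 3), tr, cfg, theta)
  expect_equal(island_log_likelihood(matrix(c(1, 2, 3), 1), tr, cfg, theta), s1)
  two <- island_log_likelihood(rbind(c(1, 2, 3), c(1, 2, 3)), tr, cfg, theta)
  expect_equal(two, 2 * s1)
  dat <- tiny_data(tr, list(i1 = c(1, 2, 3), i2 = c(3, 3, 1, 2, 2, 2)))
  cfgs <- list(i1 = cfg, i2 = iwe_config(c(0.5, 0.25, 0.25)))
  per <- tree_log_likelihood(dat, tr, cfgs, theta, per_island = TRUE)
  expect_equal(tree_log_likelihood(dat, tr, cfgs, theta), sum(per))
  expect_equal(per[["i1"]], s1)
})

test_that("compiled and reference engines agree on random instances", {
  set.seed(22)
  for (k in 1:15) {
    inst <- random_instance()
    colnames(inst$states) <- inst$tree$labels
    dat <- methyl_data(inst$states, rep("i1", nrow(inst$states)),
                       observed = setNames(inst$observed, inst$tree$labels))
    cfgs <- list(i1 = inst$config)
    llR <- tree_log_likelihood(dat, inst$tree, cfgs, inst$theta, engine = "R")
    llC <- tree_log_likelihood(dat, inst$tree, cfgs, inst$theta, engine = "cpp")
    expect_equal(llC, llR, tolerance = 1e-9)
  }
})

test_that("pruning equals brute-force enumeration on small instances", {
  set.seed(23)
  for (k in 1:30) {
    inst <- random_instance()
    m <- nrow(inst$states)
    for (j in seq_len(m)) {
      ll <- site_log_likelihood(inst$states[j, ], inst$tree, inst$config,
                                inst$theta, observed = inst$observed)
      or <- oracle_site_lik(inst$states[j, ], inst$tree, inst$config,
                            inst$theta, inst$observed)
      expect_equal(ll, or, tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant to site order, island order and tip relabeling", {
  set.seed(24)
  tr <- balanced_tree(4, lengths = runif(6, 0.2, 1))
  des <- simulation_design(tr, n_islands = 3, site_range = c(3, 6))
  sim <- simulate_dataset(des, seed = 99)
  theta <- sim$truth$theta
  base <- tree_log_likelihood(sim$data, sim$tree, sim$truth$configs, theta)
  # permute sites within islands and permute island blocks
  perm <- order(runif(nrow(sim$data$states)))
  dat2 <- methyl_data(sim$data$states[perm, ], sim$data$island[perm])
  expect_equal(tree_log_likelihood(dat2, sim$tree, sim$truth$configs, theta),
               base, tolerance = 1e-9)
  # tips-only mode: relabeling tips with identical data leaves it unchanged
  tipdat <- sim$data$states[, c("t1", "t2", "t3", "t4")]
  tipdat[] <- 1L # identical data at all tips
  obs <- setNames(rep(TRUE, 4), colnames(tipdat))
  d3 <- methyl_data(tipdat, sim$data$island, obs)
  d4 <- methyl_data(tipdat[, c(2, 1, 3, 4)],
                    sim$data$island, obs)
  cfg <- sim$truth$configs
  for (i in seq_along(cfg)) cfg[[i]]$events <- cfg[[i]]$events[0, ]
  ll3 <- tree_log_likelihood(d3, sim$tree, cfg, theta)
  ll4 <- tree_log_likelihood(d4, sim$tree, cfg, theta)
  expect_equal(ll3, ll4, tolerance = 1e-9)
})

test_that("likelihood increases with branch length for discordant two-node data", {
  tr <- function(l) two_node_tree(l)
  cfg <- iwe_config(c(0.3, 0.3, 0.4))
  theta <- global_params(r = 0, alpha = 2, mu = 0)
  lls <- vapply(c(0.01, 0.05, 0.1, 0.2), function(l) {
    site_log_likelihood(c(1, 3), tr(l), cfg, theta)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
})
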