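test_that("IWE birth and death acceptance follow the RJ formula", {
  expect_equal(iwe_birth_acceptance(0, 0, mu = 1, l = 0.5, n = 0), 0.5)
  expect_equal(iwe_birth_acceptance(0, 0, mu = 4, l = 0.5, n = 0), 1)
  expect_equal(iwe_birth_acceptance(0, 0, mu = 0, l = 0.5, n = 0), 0)
  expect_equal(iwe_death_acceptance(0, 0, mu = 1, l = 0.5, n = 1), 1)
  # uncapped birth and death ratios are exact reciprocals
  set.seed(31)
  for (k in 1:20) {
    dll <- rnorm(1); mu <- runif(1, 0.1, 3); l <- runif(1, 0.1, 2)
    n <- sample(0:3, 1)
    ratio <- exp(dll) * mu * l / (n + 1)
    expect_equal(iwe_birth_acceptance(dll, 0, mu, l, n), min(1, ratio))
    expect_equal(iwe_death_acceptance(0, dll, mu, l, n + 1), min(1, 1 / ratio))
  }
})

test_that("branch-length acceptance degenerates correctly", {
  flat <- list(m_l = 0, s_l = 1e8)
  # l' = l: only the likelihood ratio remains
  expect_equal(branch_length_acceptance(-1, -2, 0.5, 0.5, 3, 1, 10, flat),
               min(1, exp(1)))
  # equal likelihoods, no IWEs, mu*N*(l' - l) = log 2
  expect_equal(
    branch_length_acceptance(0, 0, l_new = 0.2 + log(2), l_old = 0.2,
                             n = 0, mu = 1, N = 1, prior = flat), 0.5)
  # null model formula equals the general one with n = 0, mu = 0
  p <- default_priors()
  lp <- function(l) dnorm(log(l), p$m_l, p$s_l, log = TRUE)
  expect_equal(null_branch_length_acceptance(-3, -4, lp(0.3), lp(0.8)),
               branch_length_acceptance(-3, -4, 0.3, 0.8, 0, 0, 7, p))
  expect_equal(null_branch_length_acceptance(0, 0, lp(0.5), lp(0.5)), 1)
})

test_that("credibility intervals are equal-tailed quantile intervals", {
  expect_equal(credibility_interval(rep(3.2, 50)), c(3.2, 3.2))
  set.seed(32)
  x <- rnorm(1e5)
  ci <- credibility_interval(x, 0.95)
  expect_equal(ci, c(-1.96, 1.96), tolerance = 0.03)
  expect_equal(credibility_interval(c(5, 1, 9), 1), c(1, 9))
  expect_error(credibility_interval(numeric(0)), "empty")
})

test_that("the prior-only kernel leaves every prior marginal invariant", {
  # chains started from exact prior draws stay prior-distributed
  tr <- balanced_tree(4)
  pri <- default_priors()
  set.seed(33)
  n_chain <- 1000L
  out <- matrix(NA_real_, n_chain, 4,
                dimnames = list(NULL, c("r", "la", "lmu", "ll")))
  for (k in seq_len(n_chain)) {
    init <- sample_prior_state(tr, n_islands = 3, priors = pri)
    fit <- run_mcmc(tr, data = NULL, n_islands = 3, n_sweeps = 1,
                    burn_in = 60, thin = 1, init = init,
                    cache_check_every = 0)
    out[k, ] <- c(fit$final$theta$r, log(fit$final$theta$alpha),
                  log(fit$final$theta$mu), log(fit$final$tree$length[2]))
  }
  expect_gt(ks.test(out[, "r"], "punif")$p.value, 0.01)
  expect_gt(ks.test(out[, "la"], "pnorm", pri$m_alpha, pri$s_alpha)$p.value,
            0.01)
  expect_gt(ks.test(out[, "lmu"], "pnorm", pri$m_mu, pri$s_mu)$p.value, 0.01)
  expect_gt(ks.test(out[, "ll"], "pnorm", pri$m_l, pri$s_l)$p.value, 0.01)
})

test_that("marginal prior sampling matches within-chain expectations", {
  # decoupled chains: every component alone samples its prior exactly
  tr <- balanced_tree(4)
  pri <- default_priors()
  fn <- run_mcmc(tr, data = NULL, n_islands = 4, mode = "null",
                 n_sweeps = 6e5, burn_in = 5e3, thin = 300, seed = 37,
                 cache_check_every = 0)
  for (v in grep("^loglen", names(fn$trace), value = TRUE)) {
    expect_gt(ks.test(fn$trace[[v]], "pnorm", pri$m_l, pri$s_l)$p.value, 0.01)
  }
  expect_gt(ks.test(fn$trace$r, "punif")$p.value, 0.01)
  expect_gt(ks.test(log(fn$trace$alpha), "pnorm", pri$m_alpha,
                    pri$s_alpha)$p.value, 0.01)
  # IWE counts given frozen mu and lengths are Poisson(mu * N * l)
  fp <- run_mcmc(tr, data = NULL, n_islands = 5, n_sweeps = 1e5,
                 burn_in = 2000, thin = 50, seed = 38, cache_check_every = 0,
                 moves = list(lengths = FALSE, mu = FALSE),
                 init = list(mu = 1.2, lengths = rep(0.4, 6)))
  cnt <- fp$trace$niwe.i1
  lam <- 1.2 * 5 * 0.4
  ob <- tabulate(pmin(cnt, 8) + 1L, 9)
  ex <- c(dpois(0:7, lam), 1 - ppois(7, lam))
  expect_gt(chisq.test(ob, p = ex / sum(ex))$p.value, 0.001)
  expect_lt(abs(mean(cnt) - lam), 0.15)
})

test_that("identical seeds give identical chains and null mode has no IWEs", {
  tr <- cherry_tree()
  dat <- tiny_data(tr, list(i1 = c(1, 2, 3, 1, 1, 1), i2 = c(3, 3, 3)))
  f1 <- run_mcmc(tr, dat, n_sweeps = 300, burn_in = 100, thin = 5, seed = 7)
  f2 <- run_mcmc(tr, dat, n_sweeps = 300, burn_in = 100, thin = 5, seed = 7)
  expect_identical(f1$trace, f2$trace)
  fn <- run_mcmc(tr, dat, mode = "null", n_sweeps = 300, burn_in = 100,
                 thin = 5, seed = 8)
  expect_true(all(fn$trace$mu == 0))
  expect_true(all(fn$trace[grep("^niwe\\.", names(fn$trace))] == 0))
})

test_that("cached island likelihoods track full recomputation", {
  set.seed(34)
  tr <- balanced_tree(4, lengths = runif(6, 0.2, 0.8))
  des <- simulation_design(tr, n_islands = 4, site_range = c(5, 15))
  sim <- simulate_dataset(des, seed = 35)
  fit <- run_mcmc(sim$tree, sim$data, n_sweeps = 500, burn_in = 500,
                  thin = 10, seed = 36, cache_check_every = 100)
  expect_lt(fit$max_cache_diff, 1e-9)
  # the final state's likelihood matches an independent recomputation
  ll <- tree_log_likelihood(sim$data, fit$final$tree, fit$final$configs,
                            fit$final$theta)
  expect_equal(ll, fit$loglik, tolerance = 1e-9)
})

test_that("an impossible starting configuration aborts with the island named", {
  tr <- two_node_tree()
  dat <- tiny_data(tr, list(badisl = c(1, 3)))
  expect_error(
    run_mcmc(tr, dat, init = list(r = 1), n_sweeps = 10, burn_in = 0),
    "badisl")
})
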