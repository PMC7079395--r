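test_that("SSE rate matrix has the F81 form and the triple is stationary", {
  expect_equal(unname(sse_rate_matrix(c(1, 1, 1) / 3, 0)), matrix(0, 3, 3))
  Q <- sse_rate_matrix(c(0.2, 0.3, 0.5), R = 1)
  expect_equal(unname(Q["u", ]), c(-0.8, 0.3, 0.5))
  set.seed(11)
  for (k in 1:20) {
    pi <- drop(rdirichlet3(1))
    R <- runif(1, 0, 3)
    Q <- sse_rate_matrix(pi, R)
    expect_equal(unname(rowSums(Q)), rep(0, 3), tolerance = 1e-12)
    expect_equal(drop(pi %*% Q), rep(0, 3) , tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(sse_rate_matrix(c(0.5, 0.6, 0.1), 1), "sum to 1")
  expect_error(sse_rate_matrix(c(0.2, 0.3, 0.5), -1), "nonnegative")
})

test_that("SSE transition matrix matches the matrix exponential", {
  pi <- c(0.2, 0.3, 0.5)
  expect_equal(unname(sse_transition_matrix(pi, 2, 0)), diag(3))
  P <- sse_transition_matrix(pi, R = 2, dt = 0.5)
  expect_equal(P["u", "p"], (1 - exp(-1)) * 0.3)
  expect_equal(P["u", "u"], 0.2 + 0.8 * exp(-1))
  # equilibrium limit
  Pinf <- sse_transition_matrix(pi, R = 1, dt = 1e4)
  for (i in 1:3) expect_equal(unname(Pinf[i, ]), pi, tolerance = 1e-12)
  set.seed(12)
  for (k in 1:100) {
    pi <- drop(rdirichlet3(1))
    R <- runif(1, 0, 4)
    dt <- runif(1, 0, 3)
    P <- sse_transition_matrix(pi, R, dt)
    expect_lt(max(abs(P - oracle_P(pi, R, dt))), 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, 3), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  expect_error(sse_transition_matrix(pi, 1, -0.1), "nonnegative")
})

test_that("IWE matrices move the old equilibrium exactly onto the new one", {
  pi <- c(0.5, 0.3, 0.2)
  expect_equal(unname(iwe_transition_matrix(pi, pi)), diag(3))
  # one frequency increases
  M <- iwe_transition_matrix(c(0.5, 0.3, 0.2), c(0.7, 0.2, 0.1))
  expect_equal(unname(M["p", ]), c(1 / 3, 2 / 3, 0))
  expect_equal(unname(M["m", ]), c(0.5, 0, 0.5))
  expect_equal(unname(M["u", ]), c(1, 0, 0))
  expect_equal(drop(c(0.5, 0.3, 0.2) %*% M), c(0.7, 0.2, 0.1),
               ignore_attr = TRUE)
  # one frequency decreases
  M2 <- iwe_transition_matrix(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2))
  expect_equal(drop(c(0.7, 0.2, 0.1) %*% M2), c(0.5, 0.3, 0.2),
               ignore_attr = TRUE)
  expect_equal(unname(M2["p", ]), c(0, 1, 0))
  # tie: an unchanged frequency keeps its state
  M3 <- iwe_transition_matrix(c(0.4, 0.3, 0.3), c(0.5, 0.3, 0.2))
  expect_equal(unname(M3["p", ]), c(0, 1, 0))
  expect_equal(drop(c(0.4, 0.3, 0.3) %*% M3), c(0.5, 0.3, 0.2),
               ignore_attr = TRUE)
  expect_equal(unname(M3), oracle_M(c(0.4, 0.3, 0.3), c(0.5, 0.3, 0.2)))
  set.seed(13)
  for (k in 1:1000) {
    po <- drop(rdirichlet3(1)); pn <- drop(rdirichlet3(1))
    M <- iwe_transition_matrix(po, pn)
    expect_lt(max(abs(drop(po %*% M) - pn)), 1e-12)
    expect_equal(unname(rowSums(M)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(M >= 0))
    expect_equal(unname(M), oracle_M(po, pn), tolerance = 1e-12)
  }
  expect_error(iwe_transition_matrix(c(0, 0.5, 0.5), c(0.2, 0.4, 0.4)),
               "zero component")
})

test_that("gamma discretization returns renormalized slice means", {
  # tight gamma: all categories at the mean
  expect_equal(discretize_gamma(1e6), rep(1, 3), tolerance = 1e-2)
  # numerical-integration oracle at several shapes
  for (a in c(0.3, 1, 2.5)) {
    g <- discretize_gamma(a)
    expect_equal(g, oracle_disc_gamma(a), tolerance = 1e-9)
    expect_lt(abs(mean(g) - 1), 1e-9)
    expect_true(all(diff(g) > 0) && all(g > 0))
  }
  expect_error(discretize_gamma(0), "positive")
  rm <- rate_model(0.3, 1)
  expect_equal(rm$rates[1], 0)
  expect_equal(rm$probs, c(0.3, rep(0.7 / 3, 3)))
  expect_equal(sum(rm$rates * rm$probs), 0.7, tolerance = 1e-9) # E[R] = 1 - r
})

test_that("interval composition matches step-by-step Monte-Carlo propagation", {
  pi0 <- c(0.2, 0.3, 0.5)
  P0 <- sse_transition_matrix(pi0, 1, 0.4)
  expect_equal(compose_interval_transition(P0), P0)
  # identity IWE: composition collapses to one longer interval
  P1 <- sse_transition_matrix(pi0, 1, 0.6)
  expect_equal(
    compose_interval_transition(P0, list(list(M = diag(3), P = P1))),
    unname(sse_transition_matrix(pi0, 1, 1.0)), ignore_attr = TRUE)
  # two events with distinct triples vs simulation
  pi1 <- c(0.6, 0.3, 0.1); pi2 <- c(0.25, 0.5, 0.25)
  ev <- list(list(M = iwe_transition_matrix(pi0, pi1),
                  P = sse_transition_matrix(pi1, 1, 0.5)),
             list(M = iwe_transition_matrix(pi1, pi2),
                  P = sse_transition_matrix(pi2, 1, 0.7)))
  A <- compose_interval_transition(P0, ev)
  set.seed(14)
  n <- 1e5
  for (start in 1:3) {
    s <- rep(start, n)
    step <- function(s, P) {
      out <- s
      for (i in 1:3) {
        idx <- which(s == i)
        if (length(idx)) out[idx] <- sample.int(3, length(idx), TRUE, P[i, ])
      }
      out
    }
    s <- step(s, P0)
    for (e in ev) { s <- step(s, e$M); s <- step(s, e$P) }
    emp <- tabulate(s, 3) / n
    expect_lt(max(abs(emp - A[start, ])), 4 * sqrt(0.25 / n) + 1e-3)
  }
})

test_that("the silent-SSE fraction is minimized at the simplex center at 1/3", {
  f <- function(x) { # softmax parametrization of the simplex
    p <- exp(c(x, 0)); p <- p / sum(p); sum(p^2)
  }
  opt <- optim(c(0.3, -0.2), f)
  expect_equal(opt$value, 1 / 3, tolerance = 1e-6)
  expect_equal(sum(rep(1 / 3, 3)^2), 1 / 3)
  set.seed(15)
  pts <- rdirichlet3(500)
  expect_true(all(rowSums(pts^2) >= 1 / 3))
})
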