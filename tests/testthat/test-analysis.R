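test_that("Hamming distance counts discordant non-missing positions", {
  a <- c("u", "p", "m", NA, "u")
  expect_equal(hamming_distance(a, a)$count, 0)
  b <- c("p", "u", "u", "m", "m")
  h <- hamming_distance(a, b)
  expect_equal(h$count, 4)
  expect_equal(h$compared, 4)
  expect_equal(h$proportion, 1)
  expect_error(hamming_distance(c(NA, "u"), c("u", NA)), "comparable")
  set.seed(61)
  x <- sample(c(methyl_states, NA), 200, replace = TRUE)
  y <- sample(c(methyl_states, NA), 200, replace = TRUE)
  ok <- !is.na(x) & !is.na(y)
  expect_equal(hamming_distance(x, y)$count, sum(x[ok] != y[ok]))
  # metric properties on complete vectors
  for (k in 1:20) {
    v <- replicate(3, sample(methyl_states, 30, replace = TRUE),
                   simplify = FALSE)
    d <- function(p, q) hamming_distance(p, q)$count
    expect_equal(d(v[[1]], v[[2]]), d(v[[2]], v[[1]]))
    expect_lte(d(v[[1]], v[[3]]), d(v[[1]], v[[2]]) + d(v[[2]], v[[3]]))
  }
})

test_that("euclidean mean distance uses the 0/0.5/1 encoding per island", {
  isl <- rep(c("a", "b"), each = 4)
  x <- rep("u", 8); y <- rep("m", 8)
  expect_equal(euclidean_mean_distance(x[1:4], y[1:4], isl[1:4]), 1)
  expect_equal(euclidean_mean_distance(x, x, isl), 0)
  expect_equal(euclidean_mean_distance(x, y, isl), sqrt(2))
  set.seed(62)
  a <- sample(methyl_states, 60, replace = TRUE)
  b <- sample(methyl_states, 60, replace = TRUE)
  g <- rep(1:5, each = 12)
  enc <- function(s) (match(s, methyl_states) - 1) / 2
  brute <- sqrt(sum((tapply(enc(a), g, mean) - tapply(enc(b), g, mean))^2))
  expect_equal(euclidean_mean_distance(a, b, g), brute)
  # invariant to site order within islands
  perm <- c(sample(1:12), 12 + sample(1:48))
  expect_equal(euclidean_mean_distance(a[perm], b[perm], g[perm]),
               brute)
})

test_that("no-intercept regression returns the closed-form slope and fit", {
  # lm warns about the exact fit; only the coefficients matter here
  fit <- suppressWarnings(time_regression_fit(c(2, 4), c(1, 2)))
  expect_equal(fit$slope, 2)
  expect_equal(fit$adj_r_squared, 1)
  set.seed(63)
  x <- runif(20, 1, 5); y <- 0.7 * x + rnorm(20, 0, 0.3)
  fit <- time_regression_fit(y, x)
  expect_equal(fit$slope, sum(x * y) / sum(x^2))
  lmfit <- lm(y ~ x + 0)
  expect_equal(fit$adj_r_squared, summary(lmfit)$adj.r.squared)
  expect_error(time_regression_fit(c(1, 2), c(0, 0)), "all zero")
})

test_that("coverage evaluation reports exact hit counts per class", {
  fake_trace <- function(center) {
    data.frame(sweep = 1:50, loglik = 0, r = center$r + seq(-.01, .01, length = 50),
               alpha = center$alpha * exp(seq(-.01, .01, length = 50)),
               mu = center$mu * exp(seq(-.01, .01, length = 50)),
               loglen.A = log(center$lA) + seq(-.01, .01, length = 50),
               loglen.B = log(center$lB) + seq(-.01, .01, length = 50),
               niwe.A = 0, niwe.B = 0, nislands.A = 0, nislands.B = 0)
  }
  truth <- list(theta = global_params(0.4, 1.2, 0.5),
                lengths = c(A = 0.3, B = 0.7))
  hit <- list(truth = truth,
              fit = fake_trace(list(r = .4, alpha = 1.2, mu = .5,
                                    lA = .3, lB = .7)))
  miss <- list(truth = truth,
               fit = fake_trace(list(r = .9, alpha = 9, mu = 9,
                                     lA = 9, lB = 9)))
  rep_hit <- coverage_evaluation(list(hit, hit))
  expect_true(all(rep_hit$by_class$coverage == 1))
  rep_miss <- coverage_evaluation(list(miss))
  expect_true(all(rep_miss$by_class$coverage == 0))
  both <- coverage_evaluation(list(hit, miss))
  ov <- both$by_class[both$by_class$class == "overall", ]
  expect_equal(ov$covered, 5)  # 5 parameters hit out of 10
  expect_equal(ov$n, 10)
  # totals conserved across classes
  cls <- both$by_class[both$by_class$class != "overall", ]
  expect_equal(sum(cls$n), ov$n)
  expect_equal(sum(cls$covered), ov$covered)
  bad <- list(truth = list(theta = truth$theta, lengths = c(X = 1)),
              fit = hit$fit)
  expect_error(coverage_evaluation(list(bad)), "match")
})

test_that("per-branch IWE-rate intervals are corrected and scale-equivariant", {
  set.seed(64)
  n <- 2000
  trc <- data.frame(sweep = 1:n, loglik = 0, r = .5, alpha = 1, mu = 1,
                    loglen.A = log(0.5), loglen.B = log(0.25),
                    niwe.A = rpois(n, 4) + 1L, niwe.B = 0L,
                    nislands.A = 1, nislands.B = 0)
  iv <- iwe_rate_intervals(trc)
  expect_true(iv$flagged[iv$branch == "B"])
  expect_false(iv$flagged[iv$branch == "A"])
  # quantile oracle for branch A at the Bonferroni-adjusted level
  lev <- 1 - 0.05 / 2
  lr <- log(trc$niwe.A) - log(0.5)
  expect_equal(unlist(iv[iv$branch == "A", c("low", "high")]),
               quantile(lr, c((1 - lev) / 2, 1 - (1 - lev) / 2)),
               ignore_attr = TRUE)
  # doubling lengths shifts the log-ratio down by log 2
  trc2 <- trc
  trc2$loglen.A <- trc$loglen.A + log(2)
  trc2$loglen.B <- trc$loglen.B + log(2)
  iv2 <- iwe_rate_intervals(trc2)
  expect_equal(iv2$low, iv$low - log(2))
  expect_equal(iv2$high, iv$high - log(2))
  # single branch: no correction
  iv1 <- iwe_rate_intervals(trc[c("sweep", "loglik", "r", "alpha", "mu",
                                  "loglen.A", "niwe.A", "nislands.A")])
  lr1 <- quantile(lr, c(0.025, 0.975))
  expect_equal(unlist(iv1[c("low", "high")]), lr1, ignore_attr = TRUE)
})
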