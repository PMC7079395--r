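# Independent oracles used by the tests: matrix exponential by truncated
# series (scaling and squaring), literal case matrices for island-wide
# events, slice means by numerical integration, and a brute-force site
# likelihood that enumerates all hidden states. These deliberately avoid
# the closed forms and the pruning recursion used by the package.

oracle_Q <- function(pi, R) {
  R * matrix(c(-pi[2] - pi[3], pi[2], pi[3],
               pi[1], -pi[1] - pi[3], pi[3],
               pi[1], pi[2], -pi[1] - pi[2]),
             nrow = 3, byrow = TRUE)
}

oracle_expm <- function(A, nterm = 40L) {
  s <- max(0L, ceiling(log2(max(1e-300, max(abs(A))))) + 2L)
  B <- A / 2^s
  X <- diag(3); term <- diag(3)
  for (k in seq_len(nterm)) {
    term <- term %*% B / k
    X <- X + term
  }
  for (k in seq_len(s)) X <- X %*% X
  X
}

oracle_P <- function(pi, R, dt) oracle_expm(oracle_Q(pi, R) * dt)

oracle_M <- function(po, pn) {
  d <- pn - po
  if (sum(d > 0) == 1 && sum(d < 0) == 2) {
    b <- which(d > 0); a1 <- which(d < 0)[1]; a2 <- which(d < 0)[2]
    M <- diag(3)
    M[a1, a1] <- pn[a1] / po[a1]; M[a1, b] <- (po[a1] - pn[a1]) / po[a1]
    M[a2, a2] <- pn[a2] / po[a2]; M[a2, b] <- (po[a2] - pn[a2]) / po[a2]
    M
  } else if (sum(d < 0) == 1 && sum(d > 0) == 2) {
    a <- which(d < 0); b1 <- which(d > 0)[1]; b2 <- which(d > 0)[2]
    M <- diag(3)
    M[a, a] <- pn[a] / po[a]
    M[a, b1] <- (pn[b1] - po[b1]) / po[a]
    M[a, b2] <- (pn[b2] - po[b2]) / po[a]
    M
  } else { # ties: unchanged states keep their state
    M <- diag(3)
    inc <- which(d > 0); dec <- which(d < 0)
    for (a in dec) { M[a, a] <- pn[a] / po[a]; M[a, inc] <- 1 - M[a, a] }
    M
  }
}

# slice means of a mean-1 gamma by numerical integration, renormalized
oracle_disc_gamma <- function(alpha, K = 3) {
  q <- qgamma((0:K) / K, shape = alpha, rate = alpha)
  g <- vapply(seq_len(K), function(i) {
    K * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                  q[i], q[i + 1], rel.tol = 1e-12)$value
  }, numeric(1))
  g / mean(g)
}

# transition matrix over one branch for a fixed rate: explicit interval
# chain with intermediate-state sums
oracle_branch_matrix <- function(l, R, pi_start, events) {
  t <- c(0, events$pos, l)
  mats <- list(oracle_P(pi_start, R, t[2] - t[1]))
  pi_prev <- pi_start
  for (k in seq_len(nrow(events))) {
    pi_k <- c(events$pi_u[k], events$pi_p[k], events$pi_m[k])
    mats <- c(mats, list(oracle_M(pi_prev, pi_k)),
              list(oracle_P(pi_k, R, t[k + 2] - t[k + 1])))
    pi_prev <- pi_k
  }
  # chain the matrices by explicit summation over intermediate states
  out <- matrix(0, 3, 3)
  chain_prob <- function(i, j, mats) {
    if (length(mats) == 1L) return(mats[[1]][i, j])
    sum(vapply(1:3, function(k) {
      mats[[1]][i, k] * chain_prob(k, j, mats[-1])
    }, numeric(1)))
  }
  for (i in 1:3) for (j in 1:3) out[i, j] <- chain_prob(i, j, mats)
  out
}

# brute-force site likelihood: enumerate states of all nodes whose state
# is not pinned by an observation, for each rate category
oracle_site_lik <- function(states, tree, config, theta, observed) {
  g <- oracle_disc_gamma(theta$alpha)
  rates <- c(0, g)
  probs <- c(theta$r, rep((1 - theta$r) / 3, 3))
  ev <- config$events
  setup_pi <- function() {
    # triple in force at each node's child end
    pi_at <- matrix(NA_real_, 3, tree$n_nodes)
    pi_at[, tree$root] <- config$root_pi
    for (node in tree$preorder) {
      if (node == tree$root) next
      rows <- which(ev$branch == node)
      pi_at[, node] <- if (length(rows)) {
        k <- rows[which.max(ev$pos[rows])]
        c(ev$pi_u[k], ev$pi_p[k], ev$pi_m[k])
      } else pi_at[, tree$parent[node]]
    }
    pi_at
  }
  pi_at <- setup_pi()
  free <- which(!(observed & !is.na(states)))
  fixed <- setdiff(seq_len(tree$n_nodes), free)
  total <- 0
  for (c_idx in seq_along(rates)) {
    if (probs[c_idx] == 0) next
    R <- rates[c_idx]
    bm <- lapply(seq_len(tree$n_nodes), function(node) {
      if (node == tree$root) return(NULL)
      rows <- which(ev$branch == node)
      rows <- rows[order(ev$pos[rows])]
      oracle_branch_matrix(tree$length[node], R,
                           pi_at[, tree$parent[node]],
                           ev[rows, , drop = FALSE])
    })
    grid <- if (length(free)) {
      as.matrix(expand.grid(rep(list(1:3), length(free))))
    } else matrix(integer(0), 1, 0)
    lik_c <- 0
    for (gidx in seq_len(nrow(grid))) {
      z <- integer(tree$n_nodes)
      z[fixed] <- states[fixed]
      if (length(free)) z[free] <- grid[gidx, ]
      p <- config$root_pi[z[tree$root]]
      for (node in seq_len(tree$n_nodes)) {
        if (node == tree$root) next
        p <- p * bm[[node]][z[tree$parent[node]], z[node]]
      }
      lik_c <- lik_c + p
    }
    total <- total + probs[c_idx] * lik_c
  }
  log(total)
}

# random small problem instance for oracle-equivalence checks
random_instance <- function(max_nodes = 4, max_iwes = 2, max_sites = 2,
                            allow_missing = TRUE) {
  n <- sample(2:max_nodes, 1)
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1L, 1), integer(1)))
  len <- c(NA, runif(n - 1, 0.05, 1.5))
  tree <- iwesse_tree(parent, len, paste0("n", 1:n))
  bn <- branch_nodes(tree)
  h <- sample(0:max_iwes, 1)
  events <- if (h > 0) {
    b <- bn[sample.int(length(bn), h, replace = TRUE)]
    tr <- rdirichlet3(h)
    data.frame(branch = b, pos = runif(h) * tree$length[b],
               pi_u = tr[, 1], pi_p = tr[, 2], pi_m = tr[, 3])
  } else NULL
  config <- iwe_config(drop(rdirichlet3(1)), events)
  theta <- global_params(r = runif(1, 0, 0.8), alpha = exp(rnorm(1, 0, 0.7)),
                         mu = 0.5)
  m <- sample(1:max_sites, 1)
  states <- matrix(sample(3, m * n, replace = TRUE), m, n)
  is_tip <- lengths(tree$children) == 0
  observed <- is_tip | runif(n) < 0.6
  if (allow_missing) {
    miss <- matrix(runif(m * n) < 0.15, m, n)
    states[miss] <- NA
    states[, !observed][is.na(states[, !observed])] <- 1 # irrelevant anyway
  }
  # tips must have a state column even if NA (missing tips are ambiguous)
  list(tree = tree, config = config, theta = theta, states = states,
       observed = observed)
}
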