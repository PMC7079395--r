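#' Draw from a Dirichlet(1,1,1) distribution
#'
#' Uniform distribution on the 2-simplex; used for island root triples and
#' IWE triples.
#'
#' @param n number of draws.
#' @return `n` x 3 matrix of triples.
#' @export
rdirichlet3 <- function(n) {
  x <- matrix(rexp(3 * n), ncol = 3)
  x / rowSums(x)
}

#' Simulation design
#'
#' Bundles the fixed conditions of a simulation study: the tree shape,
#' the number of islands, the range of island sizes (site counts drawn
#' uniformly from it) and the prior hyperparameters from which the
#' generating parameters are sampled.
#'
#' @param tree an [iwesse_tree()] giving the tree shape (its branch
#'   lengths are replaced by prior draws).
#' @param n_islands number of CpG islands.
#' @param site_range integer range `c(min, max)` of sites per island.
#' @param priors see [default_priors()].
#' @return object of class `sim_design`.
#' @export
simulation_design <- function(tree = balanced_tree(4), n_islands = 100L,
                              site_range = c(10L, 400L),
                              priors = default_priors()) {
  stopifnot(site_range[1] >= 1L, site_range[2] >= site_range[1])
  structure(list(tree = tree, n_islands = as.integer(n_islands),
                 site_range = as.integer(site_range), priors = priors),
            class = "sim_design")
}

#' Sample generating parameters from the priors
#'
#' Draws log branch lengths, log gamma shape, the invariant fraction and
#' the log IWE rate from their priors, island root triples from
#' Dirichlet(1,1,1), island sizes uniformly from the design's range, and
#' a rate-factor assignment for every site (0 with probability `r`,
#' otherwise one of the three discretized-gamma rates).
#'
#' @param design a [simulation_design()].
#' @return list with `theta` ([global_params()]), `lengths` (named by
#'   branch child node), `root_pis` (matrix), `n_sites`, `rate_factors`
#'   (list per island).
#' @export
sample_design_from_priors <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  p <- design$priors
  bn <- branch_nodes(design$tree)
  lengths <- exp(rnorm(length(bn), p$m_l, p$s_l))
  names(lengths) <- design$tree$labels[bn]
  theta <- global_params(r = runif(1), alpha = exp(rnorm(1, p$m_alpha, p$s_alpha)),
                         mu = exp(rnorm(1, p$m_mu, p$s_mu)))
  n_sites <- sample(seq(design$site_range[1], design$site_range[2]),
                    design$n_islands, replace = TRUE)
  root_pis <- rdirichlet3(design$n_islands)
  g <- discretize_gamma(theta$alpha)
  rate_factors <- lapply(n_sites, function(m) {
    ifelse(runif(m) < theta$r, 0, g[sample.int(3, m, replace = TRUE)])
  })
  list(theta = theta, lengths = lengths, root_pis = root_pis,
       n_sites = n_sites, rate_factors = rate_factors)
}

#' Simulate IWE configurations
#'
#' For each island and branch, the number of IWEs is Poisson with mean
#' `mu * l`, positions are uniform on the branch and triples are
#' Dirichlet(1,1,1). Across `n_islands` islands the total count on a
#' branch is Poisson with mean `mu * n_islands * l`.
#'
#' @param tree an [iwesse_tree()] (its branch lengths are used).
#' @param mu IWE rate per island per SSE unit.
#' @param n_islands number of islands.
#' @return list of event `data.frame`s (columns `branch`, `pos`, `pi_u`,
#'   `pi_p`, `pi_m`), one per island.
#' @export
simulate_iwes <- function(tree, mu, n_islands) {
  stopifnot(mu >= 0)
  bn <- branch_nodes(tree)
  lapply(seq_len(n_islands), function(i) {
    counts <- rpois(length(bn), mu * tree$length[bn])
    tot <- sum(counts)
    if (tot == 0L) {
      return(data.frame(branch = integer(0), pos = numeric(0),
                        pi_u = numeric(0), pi_p = numeric(0), pi_m = numeric(0)))
    }
    branch <- rep(bn, counts)
    pos <- runif(tot) * tree$length[branch]
    tr <- rdirichlet3(tot)
    ev <- data.frame(branch = branch, pos = pos,
                     pi_u = tr[, 1], pi_p = tr[, 2], pi_m = tr[, 3])
    ev[order(ev$branch, ev$pos), , drop = FALSE]
  })
}

# vectorized categorical transition of a state vector by a 3x3 matrix
.transition_states <- function(states, P) {
  out <- states
  for (s in 1:3) {
    idx <- which(states == s)
    if (length(idx)) {
      out[idx] <- sample.int(3, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  out
}

# simulate one island's states down the tree; matrix mode
.sim_island_matrix <- function(tree, config, rate_f) {
  m <- length(rate_f)
  setup <- .island_branch_setup(tree, config)
  states <- matrix(NA_integer_, m, tree$n_nodes)
  states[, tree$root] <- sample.int(3, m, replace = TRUE, prob = config$root_pi)
  rate_vals <- unique(rate_f)
  for (node in tree$preorder) {
    if (node == tree$root) next
    ev <- setup$events[[node]]
    l <- tree$length[node]
    cur <- states[, tree$parent[node]]
    pi_cur <- setup$pi_at[, tree$parent[node]]
    t <- c(0, if (nrow(ev)) ev$pos, l)
    for (k in seq_len(length(t) - 1L)) {
      dt <- t[k + 1L] - t[k]
      for (R in rate_vals) {
        idx <- which(rate_f == R)
        if (dt > 0 && R > 0) {
          P <- sse_transition_matrix(pi_cur, R, dt)
          cur[idx] <- .transition_states(cur[idx], P)
        }
      }
      if (k <= nrow(ev)) {
        pi_new <- c(ev$pi_u[k], ev$pi_p[k], ev$pi_m[k])
        M <- iwe_transition_matrix(pi_cur, pi_new)
        cur <- .transition_states(cur, M)
        pi_cur <- pi_new
      }
    }
    states[, node] <- cur
  }
  states
}

# event mode: explicit exponential waiting times per site; logs per-branch
# SSE (S, silent events included) and IWE (W) counts
.sim_island_event <- function(tree, config, rate_f) {
  m <- length(rate_f)
  setup <- .island_branch_setup(tree, config)
  states <- matrix(NA_integer_, m, tree$n_nodes)
  states[, tree$root] <- sample.int(3, m, replace = TRUE, prob = config$root_pi)
  S <- W <- rep(0, tree$n_nodes)
  for (node in tree$preorder) {
    if (node == tree$root) next
    ev <- setup$events[[node]]
    l <- tree$length[node]
    W[node] <- nrow(ev)
    pi0 <- setup$pi_at[, tree$parent[node]]
    t <- c(0, if (nrow(ev)) ev$pos, l)
    for (j in seq_len(m)) {
      state <- states[j, tree$parent[node]]
      R <- rate_f[j]
      pi_cur <- pi0
      for (k in seq_len(length(t) - 1L)) {
        if (k > 1L) { # IWE at the segment start
          pi_new <- c(ev$pi_u[k - 1L], ev$pi_p[k - 1L], ev$pi_m[k - 1L])
          M <- iwe_transition_matrix(pi_cur, pi_new)
          state <- sample.int(3, 1L, prob = M[state, ])
          pi_cur <- pi_new
        }
        remaining <- t[k + 1L] - t[k]
        if (R > 0) {
          repeat {
            tau <- rexp(1L) / R
            if (tau > remaining) break
            remaining <- remaining - tau
            S[node] <- S[node] + 1
            state <- sample.int(3, 1L, prob = pi_cur)
          }
        }
      }
      states[j, node] <- state
    }
  }
  list(states = states, S = S, W = W)
}

#' Simulate methylation states down a tree
#'
#' Generates the root states of every island from its root triple and
#' propagates them from the root to the tips. In `"matrix"` mode child
#' states are drawn from the composed interval transition matrices; in
#' `"event"` mode individual SSEs (exponential waiting times at the
#' site's rate factor, each event resampling the state from the current
#' triple, silent events included) and IWE transitions are simulated and
#' counted. Both modes sample from the same distribution.
#'
#' @param tree an [iwesse_tree()] with branch lengths.
#' @param configs list of [iwe_config()] per island.
#' @param rate_factors list (per island) of per-site rate-factor values.
#' @param mode `"matrix"` or `"event"`.
#' @return a [methyl_data()] object with every node observed; in event
#'   mode it carries an attribute `event_log`: a `data.frame` with
#'   per-branch SSE counts `S` (summed over all sites and islands) and
#'   IWE counts `W` (summed over islands).
#' @export
simulate_states <- function(tree, configs, rate_factors,
                            mode = c("matrix", "event")) {
  mode <- match.arg(mode)
  stopifnot(length(configs) == length(rate_factors))
  n_isl <- length(configs)
  ids <- names(configs)
  if (is.null(ids)) ids <- sprintf("isl%03d", seq_len(n_isl))
  S <- W <- rep(0, tree$n_nodes)
  per_island <- vector("list", n_isl)
  for (i in seq_len(n_isl)) {
    .check_config(configs[[i]], tree)
    if (mode == "matrix") {
      per_island[[i]] <- .sim_island_matrix(tree, configs[[i]], rate_factors[[i]])
    } else {
      res <- .sim_island_event(tree, configs[[i]], rate_factors[[i]])
      per_island[[i]] <- res$states
      S <- S + res$S
      W <- W + res$W
    }
  }
  states <- do.call(rbind, per_island)
  colnames(states) <- tree$labels
  island <- rep(ids, vapply(per_island, nrow, integer(1)))
  out <- methyl_data(states, island)
  if (mode == "event") {
    bn <- branch_nodes(tree)
    attr(out, "event_log") <- data.frame(branch = tree$labels[bn],
                                         length = tree$length[bn],
                                         S = S[bn], W = W[bn])
  }
  out
}

#' Simulate a complete data set from the priors
#'
#' End-to-end generator of one simulation replicate: samples the
#' generating parameters from the priors, places IWEs, simulates states
#' at every node, and returns the data together with the full ground
#' truth needed for coverage evaluation.
#'
#' @param design a [simulation_design()].
#' @param seed optional integer seed.
#' @param mode passed to [simulate_states()].
#' @param mu optional fixed IWE rate overriding the prior draw (use
#'   `mu = 0` to generate data under the null model).
#' @return list with `tree` (branch lengths set to the generating
#'   values), `data` (a [methyl_data()]), and `truth` (list: `theta`,
#'   `lengths`, `configs`, `root_pis`, `rate_factors`).
#' @export
simulate_dataset <- function(design, seed = NULL, mode = "matrix", mu = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  par <- sample_design_from_priors(design)
  if (!is.null(mu)) par$theta$mu <- mu
  tree <- design$tree
  tree$length[branch_nodes(tree)] <- par$lengths
  events <- simulate_iwes(tree, par$theta$mu, design$n_islands)
  configs <- lapply(seq_len(design$n_islands), function(i) {
    iwe_config(par$root_pis[i, ], events[[i]])
  })
  names(configs) <- sprintf("isl%03d", seq_len(design$n_islands))
  data <- simulate_states(tree, configs, par$rate_factors, mode = mode)
  list(tree = tree, data = data,
       truth = list(theta = par$theta, lengths = par$lengths,
                    configs = configs, root_pis = par$root_pis,
                    rate_factors = par$rate_factors))
}
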