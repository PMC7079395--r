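#' Partial likelihood vector
#'
#' A 3-vector of conditional probabilities of the data below a point on a
#' branch given the site's state there, carried together with a separate
#' log-scale factor so that products over many branches do not underflow.
#'
#' @param w nonnegative numeric vector of length 3 (states u, p, m).
#' @param log_scale log of the factor already divided out of `w`.
#' @return object of class `partial_lik`.
#' @export
partial_lik <- function(w, log_scale = 0) {
  if (length(w) != 3L || any(w < 0) || anyNA(w)) {
    stop("partial likelihood must be 3 nonnegative finite numbers")
  }
  structure(list(w = as.numeric(w), log_scale = log_scale), class = "partial_lik")
}

.rescale_partial <- function(w, log_scale) {
  s <- max(w)
  if (s > 0 && is.finite(s)) partial_lik(w / s, log_scale + log(s))
  else partial_lik(w, log_scale)
}

#' Propagate a partial likelihood up one branch
#'
#' Transports the partial likelihood at the child end of a branch to its
#' parent end, interleaving the SSE transition matrices of the inter-event
#' intervals with the IWE transition matrices of the events on the branch
#' (for the island under consideration).
#'
#' @param omega_child a [partial_lik()] at the branch's child end.
#' @param branch_length branch length `l` in SSE units.
#' @param R the site's rate factor (>= 0).
#' @param pi_start equilibrium triple in force at the parent end of the
#'   branch (the island's triple before any event on this branch).
#' @param events `data.frame` with columns `pos` (ascending offsets from
#'   the parent end, strictly inside `(0, l)`), `pi_u`, `pi_p`, `pi_m`;
#'   `NULL` or zero rows for none.
#' @return a [partial_lik()] at the branch's parent end.
#' @export
branch_partial <- function(omega_child, branch_length, R, pi_start,
                           events = NULL) {
  stopifnot(inherits(omega_child, "partial_lik"))
  if (branch_length < 0) stop("branch length must be >= 0")
  h <- if (is.null(events)) 0L else nrow(events)
  if (h > 0L) {
    if (is.unsorted(events$pos)) stop("events must be sorted by offset")
    if (any(events$pos <= 0 | events$pos >= branch_length)) {
      stop("event offsets must lie strictly inside (0, branch length)")
    }
  }
  t <- c(0, if (h) events$pos, branch_length)
  A <- sse_transition_matrix(pi_start, R, t[2L] - t[1L])
  pi_prev <- pi_start
  if (h > 0L) for (k in seq_len(h)) {
    pi_k <- c(events$pi_u[k], events$pi_p[k], events$pi_m[k])
    A <- A %*% iwe_transition_matrix(pi_prev, pi_k) %*%
      sse_transition_matrix(pi_k, R, t[k + 2L] - t[k + 1L])
    pi_prev <- pi_k
  }
  .rescale_partial(drop(A %*% omega_child$w), omega_child$log_scale)
}

#' Combine child partial likelihoods at a node
#'
#' At a tip, returns the indicator vector of the observed state (all ones
#' for a missing observation). At an internal node, returns the entrywise
#' product of the branch-propagated child vectors, masked to the observed
#' state when the node itself is observed.
#'
#' @param child_omegas list of [partial_lik()] vectors already propagated
#'   to this node (empty for a tip).
#' @param observed_state `"u"`, `"p"`, `"m"`, `NA` (observed node with a
#'   missing value: fully ambiguous) or `NULL` (unobserved node).
#' @return a [partial_lik()].
#' @export
node_partial <- function(child_omegas = list(), observed_state = NULL) {
  mask <- rep(1, 3)
  if (!is.null(observed_state) && !is.na(observed_state)) {
    s <- if (is.character(observed_state)) match(observed_state, methyl_states)
         else as.integer(observed_state)
    if (is.na(s) || s < 1L || s > 3L) stop("invalid observed state")
    mask <- replace(rep(0, 3), s, 1)
  }
  if (!length(child_omegas)) {
    if (is.null(observed_state)) stop("a tip must carry an observation")
    return(partial_lik(mask))
  }
  w <- mask
  ls <- 0
  for (om in child_omegas) {
    stopifnot(inherits(om, "partial_lik"))
    w <- w * om$w
    ls <- ls + om$log_scale
  }
  .rescale_partial(w, ls)
}

# per-island bookkeeping: events grouped by branch with the triple in
# force at each branch's parent end (root triple modified by events on the
# path from the root)
.island_branch_setup <- function(tree, config) {
  ev <- config$events
  b <- if (nrow(ev)) .resolve_branch(ev$branch, tree) else integer(0)
  pi_at <- matrix(NA_real_, 3, tree$n_nodes)
  pi_at[, tree$root] <- config$root_pi
  by_branch <- vector("list", tree$n_nodes)
  for (node in tree$preorder) {
    if (node == tree$root) next
    rows <- which(b == node)
    rows <- rows[order(ev$pos[rows])]
    by_branch[[node]] <- ev[rows, , drop = FALSE]
    pi_at[, node] <- if (length(rows)) {
      k <- rows[length(rows)]
      c(ev$pi_u[k], ev$pi_p[k], ev$pi_m[k])
    } else pi_at[, tree$parent[node]]
  }
  list(events = by_branch, pi_at = pi_at)
}

# pruning for one site at one fixed rate factor; returns log likelihood
.site_loglik_at_rate <- function(states, tree, setup, root_pi, R, observed) {
  omegas <- vector("list", tree$n_nodes)
  for (node in tree$postorder) {
    kids <- tree$children[[node]]
    obs <- if (observed[node]) {
      s <- states[node]
      if (is.na(s)) NA else s
    } else NULL
    if (!length(kids)) {
      if (is.null(obs)) obs <- NA # unobserved tip: fully ambiguous
      omegas[[node]] <- node_partial(list(), obs)
    } else {
      up <- lapply(kids, function(ch) {
        branch_partial(omegas[[ch]], tree$length[ch], R,
                       setup$pi_at[, tree$parent[ch]],
                       setup$events[[ch]])
      })
      omegas[[node]] <- node_partial(up, obs)
    }
  }
  at_root <- omegas[[tree$root]]
  val <- sum(root_pi * at_root$w)
  if (val <= 0) -Inf else log(val) + at_root$log_scale
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log-likelihood of one CpG site
#'
#' Mixes the pruning likelihood over the four per-site rate-factor values:
#' rate 0 with probability `r` (invariant site) and each of the three
#' discretized-gamma categories with probability `(1 - r)/3`.
#'
#' @param states integer (1 = u, 2 = p, 3 = m) or character vector of
#'   length `n_nodes` in tree node order, `NA` for missing.
#' @param tree an [iwesse_tree()].
#' @param config the island's [iwe_config()].
#' @param theta a [global_params()] object.
#' @param observed logical vector of per-node observation flags (default:
#'   every node with a non-`NA` potential observation; pass explicitly for
#'   tips-only mode).
#' @param rm optional precomputed [rate_model()].
#' @return log probability of the site's data given the configuration;
#'   `-Inf` (with a warning) if the data are impossible under it.
#' @export
site_log_likelihood <- function(states, tree, config, theta,
                                observed = rep(TRUE, tree$n_nodes),
                                rm = NULL) {
  if (is.character(states)) states <- match(states, methyl_states)
  if (is.null(rm)) rm <- rate_model(theta$r, theta$alpha)
  .check_config(config, tree)
  setup <- .island_branch_setup(tree, config)
  per_rate <- vapply(rm$rates, function(R) {
    .site_loglik_at_rate(states, tree, setup, config$root_pi, R, observed)
  }, numeric(1))
  keep <- rm$probs > 0
  ll <- .logsumexp(log(rm$probs[keep]) + per_rate[keep])
  if (!is.finite(ll)) {
    warning("site has zero likelihood under the given configuration")
  }
  ll
}

#' Log-likelihood of one island
#'
#' Conditioned on the island's IWE configuration, sites are independent,
#' so the island log-likelihood is the sum of its site log-likelihoods.
#'
#' @param states integer/character matrix, sites x nodes (tree order).
#' @inheritParams site_log_likelihood
#' @return log probability of the island's data.
#' @export
island_log_likelihood <- function(states, tree, config, theta,
                                  observed = rep(TRUE, tree$n_nodes),
                                  rm = NULL) {
  if (is.character(states)) {
    states <- matrix(match(states, methyl_states), nrow = nrow(states))
  }
  if (is.null(rm)) rm <- rate_model(theta$r, theta$alpha)
  sum(vapply(seq_len(nrow(states)), function(j) {
    site_log_likelihood(states[j, ], tree, config, theta, observed, rm)
  }, numeric(1)))
}

# align a methyl_data object to tree node order; nodes without a data
# column become unobserved all-NA columns
.align_data <- function(data, tree) {
  stopifnot(inherits(data, "methyl_data"))
  unknown <- setdiff(colnames(data$states), tree$labels)
  if (length(unknown)) {
    stop("state column(s) do not match any tree node: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(tree$labels, colnames(data$states))
  states <- matrix(NA_integer_, nrow(data$states), tree$n_nodes,
                   dimnames = list(NULL, tree$labels))
  observed <- rep(FALSE, tree$n_nodes)
  have <- !is.na(idx)
  states[, have] <- data$states[, idx[have]]
  observed[have] <- data$observed[idx[have]]
  is_tip <- lengths(tree$children) == 0L
  if (any(is_tip & !observed)) {
    stop("tips must be observed: ",
         paste(tree$labels[is_tip & !observed], collapse = ", "))
  }
  list(states = states, observed = observed)
}

#' Log-likelihood of a full data set
#'
#' Islands evolve independently, so the total log-likelihood is the sum of
#' island log-likelihoods. The default engine is the compiled pruning
#' implementation; `engine = "R"` runs the reference R recursion (used for
#' cross-checking).
#'
#' @param data a [methyl_data()] object.
#' @param tree an [iwesse_tree()].
#' @param configs named list of [iwe_config()] objects, one per island id.
#' @param theta a [global_params()].
#' @param engine `"cpp"` (default) or `"R"`.
#' @param per_island if `TRUE`, return the vector of per-island
#'   log-likelihoods instead of their sum.
#' @return total log-likelihood (or per-island vector).
#' @export
tree_log_likelihood <- function(data, tree, configs, theta,
                                engine = c("cpp", "R"), per_island = FALSE) {
  engine <- match.arg(engine)
  al <- .align_data(data, tree)
  ids <- island_ids(data)
  if (!all(ids %in% names(configs))) {
    stop("missing IWE configuration for island(s): ",
         paste(setdiff(ids, names(configs)), collapse = ", "))
  }
  if (engine == "cpp") {
    ll <- .cpp_loglik(al, tree, configs[ids], data$island, theta)
  } else {
    rm <- rate_model(theta$r, theta$alpha)
    ll <- vapply(ids, function(i) {
      island_log_likelihood(al$states[data$island == i, , drop = FALSE],
                            tree, configs[[i]], theta, al$observed, rm)
    }, numeric(1))
  }
  names(ll) <- ids
  if (per_island) ll else sum(ll)
}

# marshal to the compiled pruning engine
.cpp_loglik <- function(al, tree, configs, island, theta) {
  pk <- .pack_islands(al, tree, configs, island)
  res <- cpp_tree_loglik(tree$parent - 1L, tree$length, tree$root - 1L,
                         al$observed, pk$states, pk$root_pis, pk$events,
                         theta$r, theta$alpha,
                         discretize_gamma(theta$alpha))
  as.numeric(res)
}

# split aligned states by island and convert configs to plain matrices
.pack_islands <- function(al, tree, configs, island) {
  ids <- levels(island)
  states <- lapply(ids, function(i) {
    m <- al$states[island == i, , drop = FALSE]
    m[is.na(m)] <- 0L
    m - 1L # 0-based; -1 = missing
  })
  root_pis <- lapply(ids, function(i) configs[[i]]$root_pi)
  events <- lapply(ids, function(i) {
    cfg <- configs[[i]]
    .check_config(cfg, tree)
    ev <- cfg$events
    if (!nrow(ev)) return(matrix(numeric(0), 0, 5))
    b <- .resolve_branch(ev$branch, tree)
    o <- order(b, ev$pos)
    cbind(b[o] - 1, ev$pos[o], ev$pi_u[o], ev$pi_p[o], ev$pi_m[o])
  })
  list(states = states, root_pis = root_pis, events = events)
}
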