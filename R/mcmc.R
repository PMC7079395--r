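#' Default priors
#'
#' Weakly informative priors for inference: normal priors on the log
#' branch lengths, log gamma shape and log IWE rate, and a uniform prior
#' on the invariant fraction `r`. Island root triples and IWE triples are
#' Dirichlet(1,1,1); IWE positions follow a Poisson process of intensity
#' `mu` per island per SSE unit.
#'
#' @param m_l,s_l location/scale of the normal prior on log branch length.
#' @param m_alpha,s_alpha location/scale of the normal prior on log alpha.
#' @param m_mu,s_mu location/scale of the normal prior on log mu.
#' @return list of prior hyperparameters.
#' @export
default_priors <- function(m_l = -2, s_l = 2, m_alpha = 0, s_alpha = 1,
                           m_mu = 0, s_mu = 2) {
  stopifnot(s_l > 0, s_alpha > 0, s_mu > 0)
  list(m_l = m_l, s_l = s_l, m_alpha = m_alpha, s_alpha = s_alpha,
       m_mu = m_mu, s_mu = s_mu)
}

#' Default proposal configuration
#'
#' Log branch-length proposals use a symmetric two-component Gaussian
#' mixture (mostly small steps, occasionally large jumps); `r` uses a
#' reflected uniform walk on \[0, 1\]; log alpha and log mu use Gaussian
#' walks. New IWE triples are drawn from their Dirichlet(1,1,1) prior and
#' positions uniformly on the branch, so the reversible-jump acceptance
#' ratio takes its simple closed form.
#'
#' @param w_small weight of the small-step mixture component.
#' @param sd_small,sd_big scales of the two log-length components.
#' @param step_r half-width of the reflected uniform walk for `r`.
#' @param step_log_alpha,step_log_mu Gaussian walk scales.
#' @param step_rescale scale of the joint tree-rescaling move, which
#'   multiplies every branch length by a common factor and divides `mu`
#'   by it. `mu * L` (and with it the expected IWE count) is invariant
#'   under this map, so the move travels along the ridge where island-wide
#'   events and branch lengths trade off; 0 disables it.
#' @param step_extend scale of the extend/truncate length move: a proposed
#'   longer branch keeps its events at their absolute offsets and fills
#'   the extension with events drawn from the Poisson-process prior; a
#'   shorter one truncates events beyond the new length. Prior and
#'   proposal cancel exactly, so large length jumps remain acceptable on
#'   branches carrying many events; 0 disables it.
#' @return list of proposal parameters.
#' @export
default_proposals <- function(w_small = 0.9, sd_small = 0.1, sd_big = 1.0,
                              step_r = 0.1, step_log_alpha = 0.3,
                              step_log_mu = 0.3, step_rescale = 0.4,
                              step_extend = 1.5) {
  list(w_small = w_small, sd_small = sd_small, sd_big = sd_big,
       step_r = step_r, step_log_alpha = step_log_alpha,
       step_log_mu = step_log_mu, step_rescale = step_rescale,
       step_extend = step_extend)
}

#' Acceptance probability of an IWE birth move
#'
#' For a proposed additional IWE on a branch of length `l` carrying `n`
#' IWEs of the island, with the event's position drawn uniformly and its
#' triple from the Dirichlet(1,1,1) prior, the Metropolis-Hastings
#' acceptance probability is `min(1, exp(loglik_new - loglik_old) * mu *
#' l / (n + 1))`.
#'
#' @param loglik_new,loglik_old island log-likelihood with/without the
#'   proposed event.
#' @param mu IWE rate per island per SSE unit.
#' @param l branch length.
#' @param n current number of the island's IWEs on the branch (>= 0).
#' @return acceptance probability in \[0, 1\].
#' @export
iwe_birth_acceptance <- function(loglik_new, loglik_old, mu, l, n) {
  if (mu * l <= 0) return(0)
  min(1, exp(loglik_new - loglik_old + log(mu * l) - log(n + 1)))
}

#' Acceptance probability of an IWE death move
#'
#' Removing one of `n` IWEs of an island on a branch of length `l` is the
#' reverse of the birth move: acceptance `min(1, exp(loglik_new -
#' loglik_old) * n / (mu * l))`. The uncapped birth and death ratios are
#' exact reciprocals.
#'
#' @inheritParams iwe_birth_acceptance
#' @param n number of the island's IWEs on the branch before the removal
#'   (>= 1).
#' @return acceptance probability in \[0, 1\].
#' @export
iwe_death_acceptance <- function(loglik_new, loglik_old, mu, l, n) {
  stopifnot(n >= 1)
  min(1, exp(loglik_new - loglik_old + log(n) - log(mu * l)))
}

#' Acceptance probability of a branch-length move (IWE-SSE model)
#'
#' For a symmetric proposal of a new log length, the acceptance
#' probability is `min(1, LR * (l_new/l_old)^n * exp(-mu * N * (l_new -
#' l_old)) * p(log l_new)/p(log l_old))`, where `n` is the total IWE count
#' on the branch over all islands and `N` the number of islands. On
#' acceptance the offsets of existing IWEs on the branch rescale
#' proportionally; the `(l_new/l_old)^n` factor is exactly the density
#' ratio of the rescaled Poisson process.
#'
#' @param loglik_new,loglik_old total log-likelihood at the proposed and
#'   current length.
#' @param l_new,l_old proposed and current branch length.
#' @param n total number of IWEs (all islands) on the branch.
#' @param mu IWE rate; `N` number of islands.
#' @param N number of CpG islands.
#' @param prior list with `m_l`, `s_l`: normal prior on the log length.
#' @return acceptance probability in \[0, 1\].
#' @export
branch_length_acceptance <- function(loglik_new, loglik_old, l_new, l_old,
                                     n, mu, N, prior = default_priors()) {
  if (l_new <= 0) return(0)
  la <- loglik_new - loglik_old + n * (log(l_new) - log(l_old)) -
    mu * N * (l_new - l_old) +
    dnorm(log(l_new), prior$m_l, prior$s_l, log = TRUE) -
    dnorm(log(l_old), prior$m_l, prior$s_l, log = TRUE)
  min(1, exp(la))
}

#' Acceptance probability of a branch-length move (null model)
#'
#' Without IWEs the branch-length acceptance probability reduces to
#' `min(1, LR * p(log l_new)/p(log l_old))`; it equals the IWE-SSE
#' formula with `n = 0` and `mu = 0`.
#'
#' @inheritParams branch_length_acceptance
#' @param log_prior_new,log_prior_old log prior densities of the proposed
#'   and current log length.
#' @return acceptance probability in \[0, 1\].
#' @export
null_branch_length_acceptance <- function(loglik_new, loglik_old,
                                          log_prior_new, log_prior_old) {
  min(1, exp(loglik_new - loglik_old + log_prior_new - log_prior_old))
}

#' Equal-tailed credibility interval
#'
#' @param x numeric vector of posterior samples (>= 1 value; >= 2 for a
#'   non-degenerate interval).
#' @param level credibility level in `(0, 1]`; `level = 1` gives
#'   `(min, max)`.
#' @return numeric vector `c(low, high)`.
#' @export
credibility_interval <- function(x, level = 0.95) {
  if (!length(x)) stop("empty trace")
  if (level <= 0 || level > 1) stop("level must lie in (0, 1]")
  unname(quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE))
}

#' Draw a complete sampler state from the priors
#'
#' Samples global parameters, branch lengths, island root triples and IWE
#' configurations from the prior; the result can be passed as `init` to
#' [run_mcmc()]. Starting chains from exact prior draws underlies the
#' kernel-invariance validation of the sampler: if the transition kernel
#' leaves the prior invariant, states remain prior-distributed after any
#' number of prior-only sweeps.
#'
#' @param tree an [iwesse_tree()] (topology only).
#' @param n_islands number of islands.
#' @param priors see [default_priors()].
#' @return list suitable as the `init` argument of [run_mcmc()].
#' @export
sample_prior_state <- function(tree, n_islands, priors = default_priors()) {
  bn <- branch_nodes(tree)
  lengths <- exp(rnorm(length(bn), priors$m_l, priors$s_l))
  names(lengths) <- tree$labels[bn]
  tree2 <- tree
  tree2$length[bn] <- lengths
  mu <- exp(rnorm(1, priors$m_mu, priors$s_mu))
  events <- simulate_iwes(tree2, mu, n_islands)
  rp <- rdirichlet3(n_islands)
  configs <- lapply(seq_len(n_islands), function(i)
    iwe_config(rp[i, ], events[[i]]))
  list(r = runif(1), alpha = exp(rnorm(1, priors$m_alpha, priors$s_alpha)),
       mu = mu, lengths = lengths, configs = configs)
}

# dummy one-site data set used for prior-only runs
.dummy_data <- function(tree, n_islands) {
  states <- matrix("u", n_islands, tree$n_nodes,
                   dimnames = list(NULL, tree$labels))
  methyl_data(states, island = paste0("isl", seq_len(n_islands)))
}

#' Run the reversible-jump MCMC sampler
#'
#' Samples IWE configurations, island equilibrium triples, branch lengths
#' and global parameters `(r, alpha, mu)` from their posterior given a
#' tree and methylation states. One sweep performs, per island, one IWE
#' birth/death attempt and one frequency update, then one update per
#' branch length and one per global parameter. The chain starts without
#' IWEs and with parameters at their prior means unless `init` overrides
#' this. In the null model (`mode = "null"`) `mu` is fixed at 0 and IWE
#' moves are disabled.
#'
#' @param tree an [iwesse_tree()]. Its branch lengths are not used as the
#'   starting state unless `init$lengths` requests it.
#' @param data a [methyl_data()] object, or `NULL` for a prior-only run
#'   (requires `n_islands`; implies `likelihood_off = TRUE`).
#' @param mode `"iwe-sse"` (default) or `"null"`.
#' @param n_sweeps number of post-burn-in sweeps.
#' @param burn_in number of burn-in sweeps.
#' @param thin record every `thin`-th post-burn-in sweep.
#' @param priors see [default_priors()].
#' @param proposals see [default_proposals()].
#' @param init optional list with any of `r`, `alpha`, `mu`, `lengths`
#'   (per-branch, named by child node or in [branch_nodes()] order),
#'   `configs` (list of [iwe_config()] per island).
#' @param moves optional named logical list to disable move classes:
#'   `iwe`, `lengths`, `r`, `alpha`, `mu`.
#' @param island_reps,length_reps how many passes of the per-island moves
#'   (IWE birth/death and frequency updates) and of the per-branch length
#'   updates each sweep performs. Values above 1 speed up the joint mixing
#'   of branch lengths with their event counts: with many events `n` on a
#'   branch, single length steps are confined to a scale of `1/sqrt(n)`
#'   by the Poisson-process density, so the pair only diffuses as fast as
#'   the counts do.
#' @param likelihood_off if `TRUE`, the likelihood is replaced by 1 and
#'   the chain samples the prior (used for validation).
#' @param n_islands number of islands for a prior-only run.
#' @param cache_check_every recompute all cached island log-likelihoods
#'   from scratch every this many sweeps and track the largest deviation
#'   (reported as `max_cache_diff`); 0 disables.
#' @param seed optional integer seed (`set.seed` is called if given).
#' @return an object of class `iwesse_fit`: list with `trace` (data frame
#'   with columns `sweep`, `loglik`, `r`, `alpha`, `mu`, `loglen.*`,
#'   `niwe.*`, `nislands.*` per branch), `final` (configs, theta,
#'   lengths), `accept` (per-move attempt/acceptance counts),
#'   `max_cache_diff`, `tree`, `mode`, `priors`, `proposals`.
#' @export
run_mcmc <- function(tree, data = NULL, mode = c("iwe-sse", "null"),
                     n_sweeps = 2000L, burn_in = 2000L, thin = 10L,
                     priors = default_priors(),
                     proposals = default_proposals(), init = NULL,
                     moves = list(), likelihood_off = is.null(data),
                     n_islands = NULL, cache_check_every = 1000L,
                     island_reps = 1L, length_reps = 1L, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(data)) {
    if (!likelihood_off) stop("data is required unless likelihood_off = TRUE")
    if (is.null(n_islands)) stop("prior-only runs need n_islands")
    data <- .dummy_data(tree, n_islands)
  }
  al <- .align_data(data, tree)
  ids <- island_ids(data)
  N <- length(ids)

  mv <- utils::modifyList(list(iwe = TRUE, lengths = TRUE, r = TRUE,
                               alpha = TRUE, mu = TRUE), moves)
  if (mode == "null") { mv$iwe <- FALSE; mv$mu <- FALSE }

  theta <- global_params(
    r = if (!is.null(init$r)) init$r else 0.5,
    alpha = if (!is.null(init$alpha)) init$alpha else exp(priors$m_alpha),
    mu = if (!is.null(init$mu)) init$mu
         else if (mode == "null") 0 else exp(priors$m_mu))
  bn <- branch_nodes(tree)
  lengths0 <- rep(exp(priors$m_l), length(bn))
  names(lengths0) <- tree$labels[bn]
  if (!is.null(init$lengths)) {
    il <- init$lengths
    if (!is.null(names(il))) lengths0[names(il)] <- il else lengths0[] <- il
  }
  tree0 <- tree
  tree0$length[bn] <- lengths0

  configs <- if (!is.null(init$configs)) init$configs
             else stats::setNames(lapply(seq_len(N), function(i)
               iwe_config(rep(1 / 3, 3))), ids)
  if (is.null(names(configs))) names(configs) <- ids

  pk <- .pack_islands(al, tree0, configs[ids], data$island)
  if (!likelihood_off) {
    ll0 <- cpp_tree_loglik(tree0$parent - 1L, tree0$length, tree0$root - 1L,
                           al$observed, pk$states, pk$root_pis, pk$events,
                           theta$r, theta$alpha, discretize_gamma(theta$alpha))
    if (any(!is.finite(ll0))) {
      stop("non-finite initial log-likelihood for island(s): ",
           paste(ids[!is.finite(ll0)], collapse = ", "),
           " (data impossible under the initial configuration)")
    }
  }

  ctrl <- list(n_sweeps = as.integer(n_sweeps), burn_in = as.integer(burn_in),
               thin = as.integer(thin), iwe_moves = mv$iwe,
               update_lengths = mv$lengths, update_r = mv$r,
               update_alpha = mv$alpha, update_mu = mv$mu,
               likelihood_off = likelihood_off,
               cache_check_every = as.integer(cache_check_every),
               island_reps = as.integer(island_reps),
               length_reps = as.integer(length_reps))
  pri <- list(m_l = priors$m_l, s_l = priors$s_l, m_alpha = priors$m_alpha,
              s_alpha = priors$s_alpha, m_mu = priors$m_mu, s_mu = priors$s_mu)
  res <- cpp_run_chain(tree0$parent - 1L, tree0$length, tree0$root - 1L,
                       al$observed, pk$states, pk$root_pis, pk$events,
                       theta$r, theta$alpha, theta$mu, pri, proposals, ctrl)

  blab <- tree$labels[bn]
  trace <- as.data.frame(res$trace)
  names(trace) <- c("sweep", "loglik", "r", "alpha", "mu",
                    paste0("loglen.", blab), paste0("niwe.", blab),
                    paste0("nislands.", blab))
  final_tree <- tree
  final_tree$length <- res$lengths
  fin_configs <- stats::setNames(lapply(seq_len(N), function(i) {
    E <- res$events[[i]]
    ev <- if (nrow(E)) data.frame(branch = as.integer(E[, 1]), pos = E[, 2],
                                  pi_u = E[, 3], pi_p = E[, 4], pi_m = E[, 5])
          else NULL
    iwe_config(res$root_pis[[i]], ev)
  }), ids)
  accept <- data.frame(
    move = c("iwe_birth", "iwe_death", "frequency", "branch_length",
             "r", "alpha", "mu", "rescale", "extend_truncate"),
    attempts = res$accept[, 1], accepted = res$accept[, 2])
  structure(list(trace = trace, final = list(
                   configs = fin_configs,
                   theta = global_params(res$r, res$alpha, max(res$mu, 0)),
                   tree = final_tree),
                 accept = accept, max_cache_diff = res$max_cache_diff,
                 loglik = res$loglik, tree = tree, mode = mode,
                 priors = priors, proposals = proposals,
                 branch_labels = blab),
            class = "iwesse_fit")
}

#' @export
print.iwesse_fit <- function(x, ...) {
  cat("iwesse_fit (", x$mode, " model): ", nrow(x$trace),
      " recorded sweeps\n", sep = "")
  post <- vapply(x$trace[c("r", "alpha", "mu")], mean, numeric(1))
  cat(sprintf("posterior means: r = %.3f, alpha = %.3f, mu = %.4f\n",
              post[1], post[2], post[3]))
  ni <- grep("^niwe\\.", names(x$trace))
  cat(sprintf("mean total IWE count: %.1f\n", mean(rowSums(x$trace[ni]))))
  invisible(x)
}
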