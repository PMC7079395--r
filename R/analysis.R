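#' Coverage evaluation of credibility intervals
#'
#' For a set of simulation replicates with known generating parameters
#' and fitted MCMC traces, computes how often the equal-tailed
#' credibility intervals contain the generating value, per parameter
#' class (branch lengths pooled, IWE rate, gamma shape, invariant
#' fraction), per branch position, and overall. For a correct sampler
#' the empirical coverage is consistent with the nominal level
#' (simulation-based calibration).
#'
#' @param replicates list of replicates, each a list with `truth` (the
#'   `truth` of [simulate_dataset()]) and `fit` (an [run_mcmc()] result
#'   or its trace `data.frame`).
#' @param level credibility level.
#' @return list of class `coverage_report` with `by_class` (data frame:
#'   class, n, covered, coverage and exact binomial 95% CI) and
#'   `by_branch` (per branch position across replicates).
#' @export
coverage_evaluation <- function(replicates, level = 0.95) {
  if (!length(replicates)) stop("at least one replicate is required")
  rows <- lapply(replicates, function(rep) {
    trace <- if (inherits(rep$fit, "iwesse_fit")) rep$fit$trace else rep$fit
    truth <- rep$truth
    blab <- sub("^loglen\\.", "", grep("^loglen\\.", names(trace), value = TRUE))
    if (!setequal(blab, names(truth$lengths))) {
      stop("trace branches do not match ground-truth branches")
    }
    cov1 <- function(x, true) {
      ci <- credibility_interval(x, level)
      true >= ci[1] && true <= ci[2]
    }
    len_cov <- vapply(blab, function(b) {
      cov1(trace[[paste0("loglen.", b)]], log(truth$lengths[[b]]))
    }, logical(1))
    c(stats::setNames(len_cov, paste0("length.", blab)),
      iwe_rate = cov1(trace$mu, truth$theta$mu),
      shape = cov1(trace$alpha, truth$theta$alpha),
      invariant_fraction = cov1(trace$r, truth$theta$r))
  })
  covm <- do.call(rbind, rows)
  len_cols <- grep("^length\\.", colnames(covm))
  class_members <- list(
    branch_length = colnames(covm)[len_cols],
    iwe_rate = "iwe_rate",
    shape = "shape",
    invariant_fraction = "invariant_fraction",
    overall = colnames(covm))
  by_class <- do.call(rbind, lapply(names(class_members), function(cl) {
    x <- covm[, class_members[[cl]], drop = FALSE]
    n <- length(x); k <- sum(x)
    ci <- binom.test(k, n)$conf.int
    data.frame(class = cl, n = n, covered = k, coverage = k / n,
               ci_low = ci[1], ci_high = ci[2])
  }))
  by_branch <- do.call(rbind, lapply(colnames(covm)[len_cols], function(b) {
    x <- covm[, b]
    ci <- binom.test(sum(x), length(x))$conf.int
    data.frame(branch = sub("^length\\.", "", b), n = length(x),
               covered = sum(x), coverage = mean(x),
               ci_low = ci[1], ci_high = ci[2])
  }))
  structure(list(by_class = by_class, by_branch = by_branch, level = level),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage of ", 100 * x$level, "% credibility intervals\n", sep = "")
  print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' Per-branch intervals of the IWE rate (events per length unit)
#'
#' Equal-tailed credibility intervals of `log(IWE count / branch
#' length)` per branch, with a multiple-testing correction across
#' branches (Bonferroni: each interval at level `1 - (1 - level)/K`).
#' Branches whose IWE count is zero in every recorded sweep are reported
#' on `count + 0.5` and flagged.
#'
#' @param fit an [run_mcmc()] result (or its trace `data.frame`).
#' @param level overall credibility level.
#' @param correction `"bonferroni"` or `"none"`.
#' @return `data.frame` with columns `branch`, `low`, `high`, `mean`,
#'   `flagged`.
#' @export
iwe_rate_intervals <- function(fit, level = 0.95,
                               correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  trace <- if (inherits(fit, "iwesse_fit")) fit$trace else fit
  blab <- sub("^niwe\\.", "", grep("^niwe\\.", names(trace), value = TRUE))
  K <- length(blab)
  lev <- if (correction == "bonferroni" && K > 1L) 1 - (1 - level) / K else level
  do.call(rbind, lapply(blab, function(b) {
    cnt <- trace[[paste0("niwe.", b)]]
    flagged <- all(cnt == 0)
    if (flagged) cnt <- cnt + 0.5
    lr <- log(cnt) - trace[[paste0("loglen.", b)]]
    ci <- credibility_interval(lr, lev)
    data.frame(branch = b, low = ci[1], high = ci[2],
               mean = mean(lr[is.finite(lr)]), flagged = flagged)
  }))
}

#' Hamming distance between two state sequences
#'
#' Number (and proportion) of paired positions whose non-missing states
#' differ; positions missing in either sequence are not compared.
#'
#' @param states_a,states_b equal-length vectors of states (`"u"`,
#'   `"p"`, `"m"` or integer 1..3; `NA` missing).
#' @return list with `count`, `compared` and `proportion`.
#' @export
hamming_distance <- function(states_a, states_b) {
  if (length(states_a) != length(states_b)) {
    stop("sequences must have equal length")
  }
  ok <- !is.na(states_a) & !is.na(states_b)
  if (!any(ok)) stop("no comparable (jointly non-missing) positions")
  diff <- states_a[ok] != states_b[ok]
  list(count = sum(diff), compared = sum(ok),
       proportion = sum(diff) / sum(ok))
}

#' Euclidean distance between island mean-methylation vectors
#'
#' Encodes states numerically (u = 0, p = 0.5, m = 1), averages over the
#' non-missing sites of each island, and returns the Euclidean norm of
#' the difference between the two island-mean vectors. Islands with no
#' non-missing sites in either sequence are excluded with a warning.
#'
#' @param states_a,states_b equal-length site-state vectors.
#' @param island island grouping of the sites.
#' @return nonnegative number.
#' @export
euclidean_mean_distance <- function(states_a, states_b, island) {
  enc <- function(s) {
    if (is.character(s)) s <- match(s, methyl_states)
    (as.numeric(s) - 1) / 2
  }
  a <- enc(states_a); b <- enc(states_b)
  ma <- tapply(a, island, mean, na.rm = TRUE)
  mb <- tapply(b, island, mean, na.rm = TRUE)
  ok <- is.finite(ma) & is.finite(mb)
  if (any(!ok)) {
    warning(sum(!ok), " island(s) without comparable sites excluded")
  }
  sqrt(sum((ma[ok] - mb[ok])^2))
}

#' No-intercept regression of branch lengths on time differences
#'
#' Least-squares fit through the origin of estimated branch lengths
#' against known time differences, with the adjusted R-squared as the
#' fraction of explained variance.
#'
#' @param lengths branch-length estimates.
#' @param times paired time differences (not all zero).
#' @return list with `slope` and `adj_r_squared`.
#' @export
time_regression_fit <- function(lengths, times) {
  if (length(lengths) != length(times) || length(lengths) < 2L) {
    stop("need >= 2 paired observations")
  }
  if (all(times == 0)) stop("time differences are all zero")
  fit <- stats::lm(lengths ~ times + 0)
  list(slope = unname(stats::coef(fit)[1]),
       adj_r_squared = summary(fit)$adj.r.squared)
}

#' From-prior coverage study
#'
#' Simulates `n_reps` data sets with generating parameters drawn from
#' the priors, runs the reversible-jump sampler on each, and evaluates
#' the coverage of the credibility intervals against the generating
#' values.
#'
#' @param n_reps number of replicates.
#' @param design a [simulation_design()].
#' @param n_sweeps,burn_in,thin MCMC settings per replicate.
#' @param level credibility level.
#' @param seed base seed; replicate `k` uses `seed * 1000 + k` for both
#'   simulation and inference.
#' @param verbose print one line per replicate.
#' @return list with `report` (a [coverage_evaluation()] result) and
#'   `replicates` (truth and trace per replicate).
#' @export
coverage_study <- function(n_reps = 30L, design = simulation_design(),
                           n_sweeps = 20000L, burn_in = 20000L, thin = 10L,
                           level = 0.95, seed = 1L, verbose = FALSE) {
  replicates <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    set.seed(seed * 1000 + k)
    sim <- simulate_dataset(design)
    fit <- run_mcmc(sim$tree, sim$data, mode = "iwe-sse",
                    n_sweeps = n_sweeps, burn_in = burn_in, thin = thin,
                    priors = design$priors, cache_check_every = 0L)
    replicates[[k]] <- list(truth = sim$truth, fit = fit$trace)
    if (verbose) {
      message(sprintf("replicate %d/%d: true mu=%.3g, post mean mu=%.3g",
                      k, n_reps, sim$truth$theta$mu, mean(fit$trace$mu)))
    }
  }
  list(report = coverage_evaluation(replicates, level),
       replicates = replicates)
}

#' Null-model test for island-wide events
#'
#' Simulates data sets under the null model (no IWEs; `mu = 0`), fits
#' the full IWE-SSE model to each, and summarizes how many IWEs the full
#' model infers: the posterior mean and maximum of the total IWE count,
#' and the maximum over branches of the posterior-mean percentage of
#' islands carrying an IWE on that branch. Small values indicate that
#' the IWE machinery does not hallucinate events on IWE-free data.
#'
#' @param design a [simulation_design()].
#' @param n_reps number of null replicates.
#' @param n_sweeps,burn_in,thin MCMC settings per replicate.
#' @param seed base seed (replicate `k` uses `seed * 1000 + k`).
#' @return `data.frame` with one row per replicate: `mean_total_iwe`,
#'   `max_total_iwe`, `max_edge_island_pct` (percent).
#' @export
null_iwe_test <- function(design, n_reps = 5L, n_sweeps = 3000L,
                          burn_in = 3000L, thin = 10L, seed = 1L) {
  out <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    set.seed(seed * 1000 + k)
    sim <- simulate_dataset(design, mu = 0)
    fit <- run_mcmc(sim$tree, sim$data, mode = "iwe-sse",
                    n_sweeps = n_sweeps, burn_in = burn_in, thin = thin,
                    priors = design$priors, cache_check_every = 0L)
    tr <- fit$trace
    tot <- rowSums(tr[grep("^niwe\\.", names(tr))])
    nisl <- tr[grep("^nislands\\.", names(tr))]
    edge_pct <- 100 * vapply(nisl, mean, numeric(1)) / design$n_islands
    out[[k]] <- data.frame(mean_total_iwe = mean(tot),
                           max_total_iwe = max(tot),
                           max_edge_island_pct = max(edge_pct))
  }
  do.call(rbind, out)
}
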