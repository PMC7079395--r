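#' @useDynLib iwesse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pgamma qgamma quantile rnorm runif rpois rexp rbinom
#'   dnorm sd integrate qnorm binom.test ks.test chisq.test
NULL

#' Methylation state labels
#'
#' The three observable methylation states of a CpG site: unmethylated
#' (`u`), partially methylated (`p`) and methylated (`m`). Missing
#' observations are encoded as `NA` throughout the package.
#'
#' @format Character vector of length 3.
#' @export
methyl_states <- c("u", "p", "m")

# numerical floor below which a triple component counts as degenerate
.TRIPLE_FLOOR <- 1e-12

#' Validate an equilibrium frequency triple
#'
#' An equilibrium triple (pi_u, pi_p, pi_m) is a point on the 2-simplex:
#' the stationary probabilities of the three methylation states for a CpG
#' island during an inter-IWE interval.
#'
#' @param pi numeric vector of length 3, `(pi_u, pi_p, pi_m)`.
#' @param strict if `TRUE`, require all components strictly positive
#'   (above an internal floor of 1e-12); required wherever the triple is
#'   used as a divisor (IWE transition matrices) or as a root/IWE triple.
#' @return the triple, invisibly, after validation.
#' @export
check_triple <- function(pi, strict = FALSE) {
  if (!is.numeric(pi) || length(pi) != 3L || anyNA(pi)) {
    stop("equilibrium triple must be a numeric vector of length 3 with no NA")
  }
  if (any(pi < 0) || any(pi > 1)) {
    stop("equilibrium triple components must lie in [0, 1]")
  }
  if (abs(sum(pi) - 1) > 1e-12) {
    stop("equilibrium triple components must sum to 1 (tolerance 1e-12)")
  }
  if (strict && any(pi < .TRIPLE_FLOOR)) {
    stop("equilibrium triple has a (near-)zero component; ",
         "strictly positive components are required here")
  }
  invisible(pi)
}

#' SSE rate matrix
#'
#' Rate matrix of the single-site event (SSE) process for one CpG site: an
#' F81-style three-state process in which events occur at rate `R` and each
#' event resamples the state from the island's current equilibrium triple
#' `pi` (possibly resampling the current state, a "silent" SSE). The
#' off-diagonal entry (i, j) is `R * pi[j]`.
#'
#' @param pi equilibrium triple `(pi_u, pi_p, pi_m)`.
#' @param R nonnegative per-site rate factor.
#' @return 3x3 rate matrix with rows summing to 0; `pi` is a stationary
#'   left vector.
#' @examples
#' sse_rate_matrix(c(0.2, 0.3, 0.5), R = 1)
#' @export
sse_rate_matrix <- function(pi, R) {
  check_triple(pi)
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 0) {
    stop("rate factor R must be a single nonnegative number")
  }
  Q <- R * matrix(pi, nrow = 3, ncol = 3, byrow = TRUE)
  diag(Q) <- diag(Q) - R
  dimnames(Q) <- list(methyl_states, methyl_states)
  Q
}

#' SSE transition probability matrix
#'
#' Closed-form transition probabilities of the SSE process over a duration
#' `dt` at rate factor `R`: off-diagonal `(1 - exp(-R dt)) * pi[j]`,
#' diagonal `pi[i] + (1 - pi[i]) * exp(-R dt)`. Equals the matrix
#' exponential of [sse_rate_matrix()] times `dt`.
#'
#' @inheritParams sse_rate_matrix
#' @param dt nonnegative elapsed time (in SSE units).
#' @return 3x3 row-stochastic matrix.
#' @examples
#' sse_transition_matrix(c(0.2, 0.3, 0.5), R = 2, dt = 0.5)
#' @export
sse_transition_matrix <- function(pi, R, dt) {
  check_triple(pi)
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 0) {
    stop("rate factor R must be a single nonnegative number")
  }
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0) {
    stop("duration dt must be a single nonnegative number")
  }
  e <- exp(-R * dt)
  P <- (1 - e) * matrix(pi, nrow = 3, ncol = 3, byrow = TRUE)
  diag(P) <- pi + (1 - pi) * e
  dimnames(P) <- list(methyl_states, methyl_states)
  P
}

#' IWE state-transition matrix
#'
#' When an island-wide event (IWE) replaces the equilibrium triple
#' `pi_old` by `pi_new`, every site of the island transitions by a
#' minimal-motion stochastic matrix `M` chosen so that expected state
#' frequencies match `pi_new` immediately: `pi_old %*% M == pi_new`.
#' Two cases arise. If exactly one frequency increases, each decreasing
#' state keeps its state with probability `pi_new/pi_old` and otherwise
#' moves to the increasing state. If exactly one frequency decreases, that
#' state moves to each increasing state `b` with probability
#' `(pi_new[b] - pi_old[b]) / pi_old[a]` and otherwise stays. States whose
#' frequency is unchanged keep their state (both case formulas then
#' coincide).
#'
#' @param pi_old,pi_new equilibrium triples before and after the event;
#'   all components must be strictly positive.
#' @return 3x3 row-stochastic matrix `M` with `pi_old %*% M == pi_new`.
#' @examples
#' M <- iwe_transition_matrix(c(0.5, 0.3, 0.2), c(0.7, 0.2, 0.1))
#' drop(c(0.5, 0.3, 0.2) %*% M)  # == (0.7, 0.2, 0.1)
#' @export
iwe_transition_matrix <- function(pi_old, pi_new) {
  check_triple(pi_old, strict = TRUE)
  check_triple(pi_new, strict = TRUE)
  d <- pi_new - pi_old
  inc <- which(d > 0)
  dec <- which(d < 0)
  M <- diag(3)
  if (length(inc) == 0L) {
    # identical triples: no movement
  } else if (length(inc) == 1L) {
    # one state gains frequency; each losing state sheds the excess to it
    for (a in dec) {
      M[a, a] <- pi_new[a] / pi_old[a]
      M[a, inc] <- 1 - M[a, a]
    }
  } else {
    # one state loses frequency; it feeds each gaining state
    a <- dec
    if (length(a) != 1L) stop("invalid triple pair") # unreachable on simplex
    M[a, ] <- 0
    M[a, inc] <- d[inc] / pi_old[a]
    M[a, a] <- pi_new[a] / pi_old[a]
  }
  dimnames(M) <- list(methyl_states, methyl_states)
  M
}

#' Discretize a mean-1 gamma distribution into equal-probability categories
#'
#' Splits a Gamma distribution with shape `alpha` and mean 1 into `K`
#' equal-probability slices and returns the conditional mean of each slice,
#' renormalized so the category mean is exactly 1. Used for the
#' non-invariant part of the per-site rate-factor distribution.
#'
#' @param alpha gamma shape parameter, > 0.
#' @param K number of categories (default 3).
#' @return increasing numeric vector of `K` positive rates with mean 1.
#' @examples
#' discretize_gamma(0.5)
#' @export
discretize_gamma <- function(alpha, K = 3L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("gamma shape alpha must be a single positive number")
  }
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  q <- qgamma((0:K) / K, shape = alpha, rate = alpha)
  # slice mean of Gamma(a, a) over (q[i], q[i+1]) via the shape a+1 identity
  upper <- pgamma(q[-1L], shape = alpha + 1, rate = alpha)
  lower <- pgamma(q[-(K + 1L)], shape = alpha + 1, rate = alpha)
  rates <- K * (upper - lower)
  rates / mean(rates)
}

#' Invariant + discretized-gamma rate model
#'
#' Per-site rate factors: a site is invariant (rate 0) with probability
#' `r`; otherwise its rate is one of `K` discretized-gamma categories
#' (shape `alpha`, mean 1), each with probability `(1 - r)/K`.
#'
#' @param r invariant fraction in \[0, 1\].
#' @param alpha gamma shape parameter, > 0.
#' @param K number of gamma categories (default 3).
#' @return list with components `rates` (length `K + 1`, first 0) and
#'   `probs` (`c(r, rep((1 - r)/K, K))`), and the inputs `r`, `alpha`.
#' @export
rate_model <- function(r, alpha, K = 3L) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1) {
    stop("invariant fraction r must lie in [0, 1]")
  }
  rates <- c(0, discretize_gamma(alpha, K))
  probs <- c(r, rep((1 - r) / K, K))
  list(rates = rates, probs = probs, r = r, alpha = alpha)
}

#' Compose SSE intervals and IWE jumps over one branch interval
#'
#' Transition matrix between the state at the start of a branch (or branch
#' segment) and its end, when `h` IWEs fall inside it: the product
#' `P_0 (M_1 P_1) ... (M_h P_h)` of the SSE transition matrix before the
#' first event and alternating IWE / SSE matrices after each event.
#'
#' @param P0 3x3 row-stochastic SSE transition matrix of the first
#'   sub-interval.
#' @param events list of `h` pairs `list(M = <IWE matrix>, P = <SSE
#'   matrix>)` in chronological order; may be empty.
#' @return 3x3 row-stochastic matrix.
#' @export
compose_interval_transition <- function(P0, events = list()) {
  .check_stochastic(P0)
  A <- P0
  for (ev in events) {
    .check_stochastic(ev$M)
    .check_stochastic(ev$P)
    A <- A %*% ev$M %*% ev$P
  }
  A
}

.check_stochastic <- function(P) {
  if (!is.matrix(P) || any(dim(P) != 3L) || anyNA(P)) {
    stop("expected a 3x3 numeric matrix")
  }
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("matrix is not row-stochastic")
  }
  invisible(P)
}
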