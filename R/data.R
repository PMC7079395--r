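#' Observed methylation states
#'
#' Container for a sites x nodes matrix of methylation states with a
#' site-to-island grouping. States are `"u"`, `"p"`, `"m"` or `NA`
#' (missing). Each node carries an observation flag: at observed nodes the
#' recorded state constrains the likelihood; unobserved nodes are summed
#' over. Tips are always observed (missing entries at observed nodes are
#' treated as fully ambiguous).
#'
#' @param states character (or integer 1..3) matrix, rows = CpG sites,
#'   columns named by tree node labels.
#' @param island vector (length = rows) of island identifiers; sites of
#'   an island must be contiguous or not, order is irrelevant.
#' @param observed logical vector named by node label, or `NULL` for all
#'   columns observed. Nodes absent from `states` are unobserved.
#' @return an object of class `methyl_data` with integer `states`
#'   (1 = u, 2 = p, 3 = m, `NA` missing), `island` (factor) and
#'   `observed`.
#' @export
methyl_data <- function(states, island, observed = NULL) {
  if (is.null(colnames(states))) stop("state matrix must have node-name columns")
  if (nrow(states) != length(island)) {
    stop("island grouping must have one entry per site (row)")
  }
  if (is.character(states)) {
    bad <- !(states %in% methyl_states | is.na(states))
    if (any(bad)) {
      stop("invalid state value(s): ", paste(unique(states[bad]), collapse = ", "))
    }
    int <- matrix(match(states, methyl_states), nrow = nrow(states),
                  dimnames = dimnames(states))
  } else {
    int <- states
    storage.mode(int) <- "integer"
    if (any(int < 1L | int > 3L, na.rm = TRUE)) stop("integer states must be in 1..3")
  }
  if (is.null(observed)) {
    observed <- rep(TRUE, ncol(int))
    names(observed) <- colnames(int)
  } else {
    if (is.null(names(observed))) stop("observed flags must be named by node")
    observed <- observed[colnames(int)]
    if (anyNA(observed)) stop("observed flags missing for some state columns")
  }
  structure(list(states = int, island = factor(island), observed = observed),
            class = "methyl_data")
}

#' @export
print.methyl_data <- function(x, ...) {
  cat("methyl_data:", nrow(x$states), "sites in", nlevels(x$island),
      "islands x", ncol(x$states), "nodes\n")
  cat("observed nodes:", paste(colnames(x$states)[x$observed], collapse = " "), "\n")
  invisible(x)
}

#' Island identifiers of a methylation data set
#' @param data a [methyl_data()] object.
#' @return character vector of island levels, in order.
#' @export
island_ids <- function(data) levels(data$island)

#' IWE configuration for one island
#'
#' The latent configuration `W_i` of island `i`: the island's equilibrium
#' triple at the root, plus a list of island-wide events, each placed on a
#' branch at a time offset from the branch's parent end and carrying the
#' new equilibrium triple that applies from the event onward (down the
#' subtree, until a later event).
#'
#' @param root_pi equilibrium triple at the root (strictly positive).
#' @param events `data.frame` with columns `branch` (child-node index or
#'   label), `pos` (offset in `(0, branch length)`), `pi_u`, `pi_p`,
#'   `pi_m`; zero rows for no events.
#' @return object of class `iwe_config`.
#' @export
iwe_config <- function(root_pi, events = NULL) {
  check_triple(root_pi, strict = TRUE)
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(branch = integer(0), pos = numeric(0),
                         pi_u = numeric(0), pi_p = numeric(0), pi_m = numeric(0))
  }
  need <- c("branch", "pos", "pi_u", "pi_p", "pi_m")
  if (!all(need %in% names(events))) {
    stop("event table needs columns: ", paste(need, collapse = ", "))
  }
  events <- events[order(events$branch, events$pos), need, drop = FALSE]
  row.names(events) <- NULL
  structure(list(root_pi = as.numeric(root_pi), events = events),
            class = "iwe_config")
}

#' Global model parameters
#'
#' @param r invariant-site fraction in \[0, 1\].
#' @param alpha gamma shape of the rate-heterogeneity distribution, > 0.
#' @param mu IWE rate per island per SSE time unit, >= 0.
#' @return object of class `global_params`.
#' @export
global_params <- function(r, alpha, mu) {
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (alpha <= 0) stop("alpha must be > 0")
  if (mu < 0) stop("mu must be >= 0")
  structure(list(r = r, alpha = alpha, mu = mu), class = "global_params")
}

# resolve an event table's branch column to node indices
.resolve_branch <- function(branch, tree) {
  if (is.character(branch)) {
    idx <- match(branch, tree$labels)
    if (anyNA(idx)) stop("unknown branch label(s): ",
                         paste(branch[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(branch)
  }
  if (any(idx == tree$root)) stop("the root node identifies no branch")
  if (any(idx < 1L | idx > tree$n_nodes)) stop("branch index out of range")
  idx
}

# validate an iwe_config against a tree (offsets within branch lengths)
.check_config <- function(config, tree) {
  ev <- config$events
  if (nrow(ev)) {
    b <- .resolve_branch(ev$branch, tree)
    l <- tree$length[b]
    if (any(ev$pos <= 0 | ev$pos >= l)) {
      stop("IWE offsets must lie strictly inside (0, branch length)")
    }
    for (k in seq_len(nrow(ev))) {
      check_triple(c(ev$pi_u[k], ev$pi_p[k], ev$pi_m[k]), strict = TRUE)
    }
  }
  invisible(config)
}
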