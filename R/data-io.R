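#' Categorize methylation fractions into states
#'
#' RRBS-style thresholding of per-site methylation fractions (fraction of
#' overlapping reads detected as methylated): below 10% unmethylated,
#' 10 to 80% (inclusive) partially methylated, above 80% methylated.
#'
#' @param fraction numeric vector of fractions in \[0, 1\]; `NA` allowed.
#' @return character vector of `"u"`, `"p"`, `"m"` (and `NA`).
#' @examples
#' categorize_site(c(0.05, 0.1, 0.5, 0.8, 0.95, NA))
#' @export
categorize_site <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    stop("methylation fractions must lie in [0, 1]")
  }
  out <- rep(NA_character_, length(fraction))
  out[!is.na(fraction) & fraction < 0.1] <- "u"
  out[!is.na(fraction) & fraction >= 0.1 & fraction <= 0.8] <- "p"
  out[!is.na(fraction) & fraction > 0.8] <- "m"
  out
}

#' Classify the overall methylation state of an island
#'
#' An island is unmethylated if more than 50% of its (non-missing) sites
#' are in state `u`, methylated if more than 50% are `m`, and partially
#' methylated otherwise.
#'
#' @param states character (or integer 1..3) vector of the island's site
#'   states at one node; at least one non-missing value.
#' @return `"u"`, `"p"` or `"m"`.
#' @export
classify_island_state <- function(states) {
  if (is.numeric(states)) states <- methyl_states[states]
  states <- states[!is.na(states)]
  if (!length(states)) stop("island has no non-missing site states")
  n <- length(states)
  if (sum(states == "u") > n / 2) "u"
  else if (sum(states == "m") > n / 2) "m"
  else "p"
}

#' Count island-state transitions along a branch
#'
#' Classifies every island at a parent and a child node and tabulates the
#' 3x3 table of island-state transitions (rows: parent state, columns:
#' child state). Row sums equal the parent-side state counts.
#'
#' @param parent_states,child_states character vectors of island-level
#'   states (`"u"`, `"p"`, `"m"`), or site-state matrices together with
#'   `island` to classify first.
#' @param island optional island grouping when site states are given.
#' @return 3x3 integer table with dimnames `u`, `p`, `m`.
#' @export
island_transition_summary <- function(parent_states, child_states,
                                      island = NULL) {
  if (!is.null(island)) {
    parent_states <- vapply(split(parent_states, island),
                            classify_island_state, character(1))
    child_states <- vapply(split(child_states, island),
                           classify_island_state, character(1))
  }
  table(parent = factor(parent_states, levels = methyl_states),
        child = factor(child_states, levels = methyl_states))
}

#' Write methylation states to a TSV file
#'
#' One row per CpG site with its island id and one column per node;
#' missing states are written as `NA`.
#'
#' @param data a [methyl_data()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(data, path) {
  stopifnot(inherits(data, "methyl_data"))
  chr <- matrix(methyl_states[data$states], nrow = nrow(data$states),
                dimnames = dimnames(data$states))
  df <- data.frame(island = as.character(data$island), chr,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read methylation states from a TSV file
#'
#' The file must have a header row; node columns must match the tree's
#' node labels when a tree is supplied. The island grouping comes either
#' from an `island` column or, when the file has `chrom` and `pos`
#' columns, from an island map.
#'
#' @param path TSV path.
#' @param tree optional [iwesse_tree()]; unknown node columns raise an
#'   error naming the column.
#' @param island_map optional [read_island_map()] result, used when the
#'   file locates sites by `chrom`/`pos`.
#' @return a [methyl_data()] object.
#' @export
read_states <- function(path, tree = NULL, island_map = NULL) {
  if (!file.exists(path)) stop("states file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  meta <- intersect(c("island", "chrom", "pos"), names(df))
  node_cols <- setdiff(names(df), meta)
  if (!is.null(tree)) {
    unknown <- setdiff(node_cols, tree$labels)
    if (length(unknown)) {
      stop("unknown node column(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  if ("island" %in% names(df)) {
    island <- df$island
  } else if (all(c("chrom", "pos") %in% names(df))) {
    if (is.null(island_map)) stop("island map required for chrom/pos input")
    island <- assign_sites_to_islands(island_map, df$chrom, as.numeric(df$pos))
  } else {
    stop("states TSV needs an 'island' column or 'chrom'+'pos' columns")
  }
  st <- as.matrix(df[node_cols])
  st[st %in% c("", "NA", ".")] <- NA
  bad <- !(st %in% methyl_states | is.na(st))
  if (any(bad)) stop("invalid state value(s): ",
                     paste(unique(st[bad]), collapse = ", "))
  methyl_data(st, island)
}

#' Read a methylation-fraction table and categorize it into states
#'
#' Reads a TSV laid out like [read_states()] but with numeric per-site
#' methylation fractions (fraction of overlapping reads detected as
#' methylated) in the node columns, applies [categorize_site()] and
#' returns the categorized data.
#'
#' @inheritParams read_states
#' @return a [methyl_data()] object.
#' @export
read_fractions <- function(path, tree = NULL, island_map = NULL) {
  if (!file.exists(path)) stop("fractions file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- intersect(c("island", "chrom", "pos"), names(df))
  node_cols <- setdiff(names(df), meta)
  if (!is.null(tree)) {
    unknown <- setdiff(node_cols, tree$labels)
    if (length(unknown)) {
      stop("unknown node column(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  if ("island" %in% names(df)) {
    island <- df$island
  } else if (all(c("chrom", "pos") %in% names(df))) {
    if (is.null(island_map)) stop("island map required for chrom/pos input")
    island <- assign_sites_to_islands(island_map, df$chrom, as.numeric(df$pos))
  } else {
    stop("fractions TSV needs an 'island' column or 'chrom'+'pos' columns")
  }
  fr <- as.matrix(df[node_cols])
  if (!is.numeric(fr)) stop("node columns must be numeric fractions")
  st <- matrix(categorize_site(fr), nrow = nrow(fr),
               dimnames = list(NULL, node_cols))
  methyl_data(st, island)
}

#' Read a BED-like CpG-island map
#'
#' Coordinates follow the BED convention: 0-based, half-open intervals.
#' Islands must not overlap within a chromosome.
#'
#' @param path path to a 3- or 4-column BED file (chrom, start, end, and
#'   an optional island name).
#' @return `data.frame` of class `island_map` with columns `chrom`,
#'   `start`, `end`, `name`.
#' @export
read_island_map <- function(path) {
  if (!file.exists(path)) stop("island map not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("island map needs at least chrom, start, end")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$name <- if (ncol(df) >= 4L) as.character(df[[4L]])
             else paste0(df$chrom, ":", df$start, "-", df$end)
  df <- df[c("chrom", "start", "end", "name")]
  if (any(df$end <= df$start)) stop("island intervals must satisfy start < end")
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping islands on ", ch)
    }
  }
  class(df) <- c("island_map", "data.frame")
  df
}

#' Assign genomic sites to islands
#'
#' @param map an [read_island_map()] result.
#' @param chrom,pos site coordinates (`pos` 0-based, as in BED).
#' @return character vector of island names; sites outside every island
#'   raise an error reporting their coordinates.
#' @export
assign_sites_to_islands <- function(map, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (k in seq_len(nrow(map))) {
    hit <- chrom == map$chrom[k] & pos >= map$start[k] & pos < map$end[k]
    out[hit] <- map$name[k]
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("site outside every island: ", chrom[bad], ":", pos[bad])
  }
  out
}

#' Write an MCMC trace with a metadata sidecar
#'
#' The trace is written as CSV (one row per recorded sweep); run metadata
#' (model mode, priors, proposal configuration, branch labels) goes into
#' a JSON sidecar next to it.
#'
#' @param fit an [run_mcmc()] result.
#' @param path CSV output path; the sidecar is `<path>.meta.json`.
#' @param seed optional seed to record in the metadata.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "iwesse_fit"))
  utils::write.csv(fit$trace, path, row.names = FALSE)
  meta <- list(mode = fit$mode, priors = fit$priors,
               proposals = fit$proposals, branches = fit$branch_labels,
               seed = seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an MCMC trace CSV
#' @param path CSV path written by [write_trace()].
#' @return `data.frame`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  utils::read.csv(path, check.names = FALSE)
}

#' Write a simulation ground truth as JSON
#'
#' @param truth the `truth` component of [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(theta = unclass(truth$theta),
              lengths = as.list(truth$lengths),
              root_pis = truth$root_pis,
              configs = lapply(truth$configs, function(cf) {
                list(root_pi = cf$root_pi, events = cf$events)
              }),
              rate_factors = truth$rate_factors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a simulation ground truth JSON
#' @param path path written by [write_ground_truth()].
#' @return list with `theta`, `lengths`, `root_pis`, `configs`,
#'   `rate_factors`.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("ground truth file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  configs <- lapply(obj$configs, function(cf) {
    ev <- as.data.frame(cf$events)
    iwe_config(as.numeric(cf$root_pi), if (nrow(ev)) ev else NULL)
  })
  list(theta = global_params(obj$theta$r, obj$theta$alpha, obj$theta$mu),
       lengths = unlist(obj$lengths),
       root_pis = as.matrix(obj$root_pis),
       configs = configs,
       rate_factors = obj$rate_factors)
}
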