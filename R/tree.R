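#' Rooted tree for methylation dynamics
#'
#' Internal tree representation: nodes indexed `1..n_nodes` with parent
#' links, one root, unique node labels, and per-node branch lengths (the
#' length of the branch from the node's parent down to the node; `NA` at
#' the root). Branch lengths are in SSE units, i.e. expected single-site
#' events per CpG site.
#'
#' @param parent integer vector; `parent[i]` is the parent node of node
#'   `i`, `NA` for the root.
#' @param length numeric vector; `length[i]` is the length of the branch
#'   ending in node `i`, `NA` for the root. All lengths must be > 0.
#' @param labels character vector of unique node names.
#' @return an object of class `iwesse_tree` with components `parent`,
#'   `length`, `labels`, `root`, `children`, `preorder`, `postorder`,
#'   `n_nodes`.
#' @examples
#' tr <- iwesse_tree(parent = c(NA, 1, 1), length = c(NA, 0.3, 0.5),
#'                   labels = c("root", "A", "B"))
#' @export
iwesse_tree <- function(parent, length, labels = NULL) {
  n <- base::length(parent)
  parent <- as.integer(parent)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  if (anyDuplicated(labels)) stop("node labels must be unique")
  if (base::length(length) != n || base::length(labels) != n) {
    stop("parent, length and labels must have one entry per node")
  }
  root <- which(is.na(parent))
  if (base::length(root) != 1L) stop("tree must have exactly one root")
  if (!is.na(length[root])) stop("the root has no branch; its length must be NA")
  if (anyNA(length[-root]) || any(length[-root] <= 0)) {
    stop("branch lengths must be > 0 for all non-root nodes")
  }
  if (any(parent[-root] < 1L | parent[-root] > n)) stop("parent index out of range")
  children <- lapply(seq_len(n), function(i) which(parent == i))
  # preorder by repeated frontier expansion; also detects cycles
  preorder <- root
  frontier <- children[[root]]
  while (base::length(frontier)) {
    preorder <- c(preorder, frontier)
    frontier <- unlist(children[frontier])
  }
  if (base::length(preorder) != n) stop("tree is not connected or contains a cycle")
  structure(list(parent = parent, length = as.numeric(length),
                 labels = as.character(labels), root = root,
                 children = children, preorder = preorder,
                 postorder = rev(preorder), n_nodes = n),
            class = "iwesse_tree")
}

#' @export
print.iwesse_tree <- function(x, ...) {
  tips <- sum(lengths(x$children) == 0L)
  cat("iwesse_tree:", x$n_nodes, "nodes (", tips, "tips ), root =",
      x$labels[x$root], "\n")
  cat("total branch length:", sum(x$length, na.rm = TRUE), "SSE units\n")
  invisible(x)
}

#' Number of branches of a tree
#'
#' Branches are identified by their child node; a tree with `n` nodes has
#' `n - 1` branches.
#'
#' @param tree an [iwesse_tree()].
#' @return integer.
#' @export
n_branches <- function(tree) tree$n_nodes - 1L

#' Branch (non-root node) indices of a tree
#' @param tree an [iwesse_tree()].
#' @return integer vector of child-node indices, in preorder.
#' @export
branch_nodes <- function(tree) setdiff(tree$preorder, tree$root)

#' Convert an ape "phylo" tree
#'
#' @param phy an [ape::read.tree()] style `phylo` object with edge
#'   lengths; tip and (optionally) node labels become node names.
#' @return an [iwesse_tree()].
#' @export
as_iwesse_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  n_tip <- base::length(phy$tip.label)
  n <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n)
  len <- rep(NA_real_, n)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  len[phy$edge[, 2L]] <- phy$edge.length
  node_lab <- phy$node.label
  if (is.null(node_lab) || !base::length(node_lab)) {
    node_lab <- paste0("node", seq_len(phy$Nnode))
  }
  node_lab[node_lab == ""] <- paste0("node", which(node_lab == ""))
  iwesse_tree(parent, len, labels = c(phy$tip.label, node_lab))
}

#' Convert to an ape "phylo" tree
#'
#' @param tree an [iwesse_tree()].
#' @return an ape `phylo` object with node labels.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "iwesse_tree"))
  is_tip <- lengths(tree$children) == 0L
  n_tip <- sum(is_tip)
  # ape numbering: tips 1..n_tip, then internals starting at the root
  newid <- integer(tree$n_nodes)
  newid[is_tip] <- seq_len(n_tip)
  internals <- tree$preorder[!is_tip[tree$preorder]] # root first
  newid[internals] <- n_tip + seq_along(internals)
  child <- branch_nodes(tree)
  edge <- cbind(newid[tree$parent[child]], newid[child])
  phy <- list(edge = edge, edge.length = tree$length[child],
              Nnode = tree$n_nodes - n_tip,
              tip.label = tree$labels[order(newid[is_tip])][seq_len(n_tip)])
  phy$tip.label <- tree$labels[is_tip][order(newid[is_tip])]
  phy$node.label <- tree$labels[internals]
  class(phy) <- "phylo"
  phy
}

#' Read a rooted tree from a Newick file
#'
#' Internal nodes should be labeled in the Newick string when internal
#' methylation states are observed; unlabeled internal nodes receive
#' generated names.
#'
#' @param path path to a Newick file.
#' @return an [iwesse_tree()].
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("malformed Newick in ", path)
  as_iwesse_tree(phy)
}

#' Write a tree to a Newick file
#'
#' Branch lengths are written as decimal text with full double precision,
#' so that write/read round-trips reproduce them exactly.
#'
#' @param tree an [iwesse_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "iwesse_tree"))
  fmt <- function(node) {
    kids <- tree$children[[node]]
    inner <- if (base::length(kids)) {
      paste0("(", paste(vapply(kids, fmt, ""), collapse = ","), ")")
    } else ""
    lab <- tree$labels[node]
    len <- if (node == tree$root) "" else
      paste0(":", sprintf("%.17g", tree$length[node]))
    paste0(inner, lab, len)
  }
  writeLines(paste0(fmt(tree$root), ";"), path)
  invisible(path)
}

#' Fully balanced rooted binary tree
#'
#' Convenience constructor used by the simulator: a rooted binary tree
#' with `2^depth` tips and equal or supplied branch lengths.
#'
#' @param n_tips number of tips; must be a power of 2.
#' @param lengths branch lengths for the `2 * n_tips - 2` branches in
#'   preorder, or a single value recycled.
#' @return an [iwesse_tree()] with labels `root`, `iK` (internal), `tK`
#'   (tips).
#' @export
balanced_tree <- function(n_tips = 4L, lengths = 0.5) {
  depth <- log2(n_tips)
  if (depth != round(depth) || n_tips < 2L) stop("n_tips must be a power of 2, >= 2")
  parent <- NA_integer_; labels <- "root"
  level_nodes <- 1L
  n_int <- 0L; n_tip <- 0L
  for (d in seq_len(depth)) {
    new_nodes <- integer(0)
    for (p in level_nodes) {
      for (k in 1:2) {
        parent <- c(parent, p)
        if (d < depth) {
          n_int <- n_int + 1L
          labels <- c(labels, paste0("i", n_int))
        } else {
          n_tip <- n_tip + 1L
          labels <- c(labels, paste0("t", n_tip))
        }
        new_nodes <- c(new_nodes, base::length(parent))
      }
    }
    level_nodes <- new_nodes
  }
  n <- base::length(parent)
  len <- rep(NA_real_, n)
  len[-1L] <- rep_len(lengths, n - 1L)
  iwesse_tree(parent, len, labels)
}
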