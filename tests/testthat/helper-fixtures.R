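# small trees and data sets built in code

two_node_tree <- function(l = 1) {
  iwesse_tree(parent = c(NA, 1), length = c(NA, l), labels = c("root", "tip"))
}

cherry_tree <- function(l = c(0.4, 0.6)) {
  iwesse_tree(parent = c(NA, 1, 1), length = c(NA, l),
              labels = c("root", "A", "B"))
}

# a tiny fully observed data set on a given tree
tiny_data <- function(tree, states_by_island) {
  mats <- lapply(states_by_island, function(m) {
    matrix(m, ncol = tree$n_nodes, byrow = TRUE,
           dimnames = list(NULL, tree$labels))
  })
  st <- do.call(rbind, mats)
  methyl_data(st, rep(names(states_by_island),
                      vapply(mats, nrow, integer(1))))
}

no_iwe_config <- function(pi = c(1, 1, 1) / 3) iwe_config(pi)
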