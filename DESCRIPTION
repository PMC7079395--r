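Package: iwesse
Title: Phylogenetic Modeling of CpG-Island Methylation Dynamics with
    Island-Wide Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the evolution of CpG methylation states (unmethylated,
    partially methylated, methylated) along rooted cell-type trees with two
    kinds of events: single-site events (SSEs) that resample the state of one
    CpG from its island's equilibrium frequencies, following an F81-style
    three-state substitution process with invariant+discretized-gamma rate
    heterogeneity, and island-wide events (IWEs), a compound-Poisson process
    that redraws an island's equilibrium frequencies and simultaneously
    shifts the states of its sites by a minimal-motion stochastic matrix.
    Provides the exact pruning likelihood with IWEs interleaved on branches,
    reversible-jump Markov chain Monte Carlo inference over IWE
    configurations, branch lengths, island frequencies and global parameters,
    a null model without IWEs, a forward simulator in both transition-matrix
    and event-logging modes, readers and writers for trees, state matrices
    and island maps, RRBS methylation-fraction categorization, and
    post-inference analyses (credibility-interval coverage, per-branch IWE
    rate intervals, baseline distances).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
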