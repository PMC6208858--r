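Package: zetaphylo
Title: Distance-Based Phylogenetics Under Unknown Monotone Distortions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distance-based phylogenetic inference when the observed
    dissimilarities are an unknown monotone, subadditive distortion of an
    underlying additive (tree) metric. Provides checks for the metric axioms,
    the four-point (additivity) and ultrametric conditions, quartet split
    relations, Bandelt-Dress split decomposition with isolation indices, a
    deterministic neighbor-joining implementation, parametric
    metric-preserving transformation families (affine, stretched exponential,
    Jukes-Cantor saturation, negative-logarithmic) with exact inverses, and
    estimation of the distortion by minimizing the non-additivity residual of
    the back-transformed distance matrix over a parameter grid. Includes a
    seed-reproducible simulator for random edge-weighted trees, Markov
    sequence evolution, Hamming and log-det distances, and noise mixtures,
    plus readers and writers for PHYLIP square distance matrices, Newick
    trees, aligned FASTA and NEXUS splits blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    tibble,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
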