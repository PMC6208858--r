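# shared fixtures built in code

# the worked 4-taxon matrix and its back-transform
eq3 <- eq3_matrix()
neg_log_10 <- zeta_transform("neg_log", s = 10, m = 1)

# a random additive matrix with its generating tree
rand_additive <- function(n, seed, mean_len = 0.1) {
  tr <- random_tree(sim_config(n_leaves = n,
                               edge_length_law = list("exp", mean = mean_len),
                               seed = seed))
  list(tree = tr, D = tree_to_distances(tr))
}

# an ultrametric on 2^k taxa from a balanced clock tree, built directly
balanced_ultrametric <- function(depths = c(1, 2, 4)) {
  # three-level balanced tree: pairs at distance 2*depths[1], quartets at
  # 2*depths[2], octets at 2*depths[3]
  n <- 8
  M <- matrix(2 * depths[3], n, n)
  for (b in c(0, 4)) M[b + 1:4, b + 1:4] <- 2 * depths[2]
  for (b in seq(0, 6, by = 2)) M[b + 1:2, b + 1:2] <- 2 * depths[1]
  diag(M) <- 0
  distance_matrix(M, labels = paste0("t", 1:n))
}

# unordered split as a canonical string, for set comparisons
split_key <- function(a, b) {
  sides <- sort(c(paste(sort(a), collapse = ","),
                  paste(sort(b), collapse = ",")))
  paste(sides, collapse = " | ")
}

# nontrivial splits of an unrooted phylo tree with their edge lengths
tree_splits <- function(tr) {
  tr <- ape::unroot(tr)
  ntip <- length(tr$tip.label)
  out <- list()
  for (e in seq_len(nrow(tr$edge))) {
    desc <- tips_below(tr, tr$edge[e, 2], ntip)
    side_a <- tr$tip.label[desc]
    side_b <- setdiff(tr$tip.label, side_a)
    if (!length(side_b)) next  # root edge artifact
    out[[length(out) + 1]] <- list(key = split_key(side_a, side_b),
                                   length = tr$edge.length[e])
  }
  out
}

tips_below <- function(tr, node, ntip) {
  if (node <= ntip) return(node)
  kids <- tr$edge[tr$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tr = tr, ntip = ntip))
}
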