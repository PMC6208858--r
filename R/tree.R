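#' Neighbor joining
#'
#' A deterministic Saitou-Nei neighbor-joining implementation. At each
#' agglomeration step the pair minimizing the Q criterion is joined, with
#' ties broken toward the smallest pair of node indices (tips are numbered
#' in input label order, internal nodes in order of creation), so results
#' are identical across platforms. Negative branch-length estimates are
#' clamped to zero with the deficit moved onto the sibling edge of the same
#' join. On an additive input the algorithm recovers the generating tree's
#' topology and edge lengths exactly.
#'
#' @param D a [distance_matrix()] (or coercible matrix) with `n >= 2` taxa.
#'   Triangle-inequality violations trigger a warning, not an error.
#' @return an unrooted `ape::phylo` tree with tip labels from `D`.
#' @examples
#' tr <- neighbor_joining(eq3_matrix())
#' @export
neighbor_joining <- function(D) {
  D <- as_dm(D)
  m3 <- triangle_scan_cpp(unclass(D))
  if (m3$worst > 1e-8)
    warning("input violates the triangle inequality (worst excess ",
            format(m3$worst), "); proceeding anyway")
  res <- nj_cpp(unclass(D))
  build_phylo(res$edge, res$length, res$ntip, res$root, dm_labels(D))
}

# assemble an ape::phylo from an undirected edge list with tips 1..ntip,
# rooting at `root` and renumbering internal nodes in preorder
build_phylo <- function(edge, len, ntip, root, tip_labels) {
  nnode_total <- max(edge)
  adj <- vector("list", nnode_total)
  eid <- vector("list", nnode_total)
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1]; b <- edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); eid[[a]] <- c(eid[[a]], e)
    adj[[b]] <- c(adj[[b]], a); eid[[b]] <- c(eid[[b]], e)
  }
  newid <- integer(nnode_total)
  newid[seq_len(ntip)] <- seq_len(ntip)
  next_internal <- ntip + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  # iterative preorder from the root
  stack <- list(c(root, 0L, 0L))  # node, incoming edge id, parent newid
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr[1]; in_eid <- fr[2]; pnew <- fr[3]
    if (node > ntip) {
      newid[node] <- next_internal
      next_internal <- next_internal + 1L
    }
    if (in_eid > 0) {
      parent <- c(parent, pnew)
      child <- c(child, newid[node])
      elen <- c(elen, len[in_eid])
    }
    kids <- adj[[node]]; kide <- eid[[node]]
    keep <- kide != in_eid
    for (i in rev(which(keep)))
      stack[[length(stack) + 1]] <- c(kids[i], kide[i], newid[node])
  }
  tr <- list(edge = cbind(parent, child), edge.length = elen,
             tip.label = tip_labels, Nnode = nnode_total - ntip)
  dimnames(tr$edge) <- NULL
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Path-length distances between the leaves of a tree
#'
#' Entry `(x, y)` is the sum of edge lengths along the unique path between
#' leaves `x` and `y`; the result is an additive metric by construction.
#'
#' @param tree an `ape::phylo` tree with edge lengths.
#' @return a [distance_matrix()] over the tip labels, in tip order.
#' @export
tree_to_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no edge lengths")
  ntip <- length(tree$tip.label)
  M <- tree_path_dists_cpp(tree$edge, tree$edge.length, ntip)
  distance_matrix(M, labels = tree$tip.label, tol = Inf)
}

#' Additive-metric-consistent projection
#'
#' Maps a metric to an additive metric while fixing additive inputs: either
#' through [neighbor_joining()] followed by [tree_to_distances()]
#' (`method = "nj"`, the default, consistent for any number of taxa) or
#' through [split_decomposition_tau()] (`method = "splits"`, capped at 16
#' taxa). Both are idempotent and return matrices rather than trees because
#' the distortion-fitting objective composes the projection entrywise with a
#' transformation; the tree is recoverable via [neighbor_joining()].
#'
#' @param D a [distance_matrix()] (or coercible matrix).
#' @param method `"nj"` or `"splits"`.
#' @return an additive [distance_matrix()] with the label order of `D`.
#' @examples
#' tau(eq3_matrix())
#' @export
tau <- function(D, method = c("nj", "splits")) {
  method <- match.arg(method)
  D <- as_dm(D)
  if (method == "nj") {
    res <- nj_cpp(unclass(D))
    M <- tree_path_dists_cpp(res$edge, res$length, res$ntip)
    distance_matrix(M, labels = dm_labels(D), tol = Inf)
  } else {
    split_decomposition_tau(D)
  }
}

# fast internal tau for the fitting loop: plain matrix in, plain matrix out
tau_nj_matrix <- function(M) {
  res <- nj_cpp(M)
  tree_path_dists_cpp(res$edge, res$length, res$ntip)
}

#' Robinson-Foulds distance between unrooted trees
#'
#' The number of nontrivial splits present in exactly one of the two trees;
#' zero iff the unrooted topologies agree.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return a nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf sets differ")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Read and write Newick trees
#'
#' Thin wrappers around the `ape` Newick parser and writer. Internal node
#' labels are dropped on read; branch lengths round-trip at full precision.
#'
#' @param path file path.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree in file")
  tr$node.label <- NULL
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}
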