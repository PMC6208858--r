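#' Quartet isolation index
#'
#' For four distinct taxa split as `{i,j} | {k,l}`, the isolation index is
#' \deqn{\alpha_{ij|kl} = \tfrac12\left(\max\{s_0, s_1, s_2\} - s_0\right)}
#' where `s0 = d(i,j) + d(k,l)` is the split's own pair-sum and `s1`, `s2`
#' are the two crossing pair-sums. It is zero exactly when the split's
#' pair-sum is the (weakly) largest of the three.
#'
#' @param D a [distance_matrix()] (or coercible matrix).
#' @param ij,kl character vectors of two distinct labels each, the two sides
#'   of the quartet split.
#' @return a nonnegative number in distance units.
#' @examples
#' quartet_alpha(eq3_matrix(), c("x", "v"), c("u", "y"))  # 0.066
#' @export
quartet_alpha <- function(D, ij, kl) {
  D <- as_dm(D)
  taxa <- c(ij, kl)
  if (length(ij) != 2 || length(kl) != 2 || anyDuplicated(taxa))
    stop("need four distinct labels, two per side")
  missing <- setdiff(taxa, dm_labels(D))
  if (length(missing)) stop("unknown labels: ", paste(missing, collapse = ", "))
  s0 <- D[ij[1], ij[2]] + D[kl[1], kl[2]]
  s1 <- D[ij[1], kl[1]] + D[ij[2], kl[2]]
  s2 <- D[ij[1], kl[2]] + D[ij[2], kl[1]]
  max(0, (max(s0, s1, s2) - s0) / 2)
}

#' Isolation index of a bipartition
#'
#' The Bandelt-Dress isolation index of a split `A | B` of the taxon set is
#' the minimum over all quartets `i, j` in `A` and `k, l` in `B` (repeats
#' allowed, with `d(i,i) = 0`) of the quartet isolation index
#' [quartet_alpha()]. A positive index marks a split supported by the
#' metric; for a tree metric the splits with positive index are exactly the
#' edge-induced bipartitions, with index equal to the edge length.
#'
#' @param D a [distance_matrix()] (or coercible matrix).
#' @param A,B character vectors forming a bipartition of the taxa of `D`.
#' @return a nonnegative number in distance units.
#' @export
isolation_index <- function(D, A, B) {
  D <- as_dm(D)
  lab <- dm_labels(D)
  if (!setequal(c(A, B), lab) || length(intersect(A, B)) ||
      !length(A) || !length(B))
    stop("A and B must be a bipartition of the taxon set")
  ia <- match(A, lab); ib <- match(B, lab)
  isolation_index_idx(unclass(D), ia, ib)
}

# core computation on index sets; pairs within a side include repeats (i = j)
isolation_index_idx <- function(M, ia, ib) {
  pa <- pairs_with_repeats(ia)
  pb <- pairs_with_repeats(ib)
  # s0[p, q] = d(i,j) + d(k,l); crossing sums via vectorized lookups
  dij <- M[cbind(pa[, 1], pa[, 2])]
  dkl <- M[cbind(pb[, 1], pb[, 2])]
  best <- Inf
  for (q in seq_len(nrow(pb))) {
    k <- pb[q, 1]; l <- pb[q, 2]
    s0 <- dij + dkl[q]
    s1 <- M[pa[, 1], k] + M[pa[, 2], l]
    s2 <- M[pa[, 1], l] + M[pa[, 2], k]
    v <- (pmax(s0, s1, s2) - s0) / 2
    best <- min(best, v)
    if (best <= 0) return(0)
  }
  max(0, best)
}

pairs_with_repeats <- function(idx) {
  if (length(idx) == 1) return(cbind(idx, idx))
  rbind(cbind(idx, idx), t(combn(idx, 2)))
}

#' Enumerate all d-splits of a distance matrix
#'
#' Brute-force enumeration of every bipartition of the taxon set (hence the
#' cap at 16 taxa), keeping those with isolation index above `tol`. For an
#' additive metric the result is exactly the generating tree's edge-induced
#' splits, with indices equal to the edge lengths.
#'
#' @param D a [distance_matrix()] with at most 16 taxa.
#' @param tol splits with isolation index `<= tol` are dropped.
#' @return a tibble sorted by decreasing `alpha` with columns `side_a`,
#'   `side_b` (list columns of labels; `side_a` is the side containing the
#'   first taxon), `alpha`, and `trivial` (single-taxon side).
#' @examples
#' all_dsplits(eq3_matrix())
#' @export
all_dsplits <- function(D, tol = 1e-9) {
  D <- as_dm(D)
  lab <- dm_labels(D)
  n <- length(lab)
  if (n > 16) stop("bipartition enumeration is capped at 16 taxa")
  M <- unclass(D)
  rows <- list()
  # enumerate subsets of 2..n that join taxon 1's side's complement
  for (mask in seq_len(2^(n - 1) - 1)) {
    inB <- which(bitwAnd(bitwShiftL(1, 0:(n - 2)), mask) != 0) + 1L
    ia <- setdiff(seq_len(n), inB)
    alpha <- isolation_index_idx(M, ia, inB)
    if (alpha > tol) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        side_a = list(lab[ia]), side_b = list(lab[inB]), alpha = alpha,
        trivial = length(ia) == 1 || length(inB) == 1
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(side_a = list(), side_b = list(),
                          alpha = numeric(0), trivial = logical(0)))
  }
  out <- do.call(rbind, rows)
  key <- vapply(out$side_a, function(s) paste(sort(s), collapse = ","),
                character(1))
  out[order(-out$alpha, key), ]
}

# are two splits (given as side-a index/label sets over the same taxa)
# pairwise compatible? true iff one of the four intersections is empty
splits_compatible <- function(a1, b1, a2, b2) {
  !length(intersect(a1, a2)) || !length(intersect(a1, b2)) ||
    !length(intersect(b1, a2)) || !length(intersect(b1, b2))
}

#' Additive approximation by split decomposition
#'
#' Projects a metric onto a tree metric built from its d-splits: splits are
#' taken in decreasing order of isolation index (lexicographic tie-break on
#' the sorted side containing the first taxon) and kept greedily when
#' pairwise compatible with all previously kept splits; the output is
#' \eqn{\sum_S \alpha(S)\, \delta_S(i,j)} over the kept splits, where
#' \eqn{\delta_S(i,j) = 1} iff `S` separates `i` and `j`. Weakly compatible
#' splits beyond pairwise compatibility are reported by [all_dsplits()] but
#' excluded here so the output is always a tree metric. On an additive input
#' the map is the identity, making it an additive-metric-consistent operator.
#'
#' @inheritParams all_dsplits
#' @return a [distance_matrix()] that satisfies the four-point condition.
#' @export
split_decomposition_tau <- function(D, tol = 1e-9) {
  D <- as_dm(D)
  lab <- dm_labels(D)
  sp <- all_dsplits(D, tol = tol)
  kept_a <- list(); kept_b <- list(); kept_alpha <- numeric(0)
  for (i in seq_len(nrow(sp))) {
    a <- sp$side_a[[i]]; b <- sp$side_b[[i]]
    ok <- TRUE
    for (j in seq_along(kept_a)) {
      if (!splits_compatible(a, b, kept_a[[j]], kept_b[[j]])) { ok <- FALSE; break }
    }
    if (ok) {
      kept_a[[length(kept_a) + 1]] <- a
      kept_b[[length(kept_b) + 1]] <- b
      kept_alpha <- c(kept_alpha, sp$alpha[i])
    }
  }
  out <- matrix(0, length(lab), length(lab), dimnames = list(lab, lab))
  for (j in seq_along(kept_a)) {
    ina <- lab %in% kept_a[[j]]
    delta <- outer(ina, ina, "!=")
    out <- out + kept_alpha[j] * delta
  }
  distance_matrix(out, labels = lab, tol = Inf)
}

#' Write splits as a NEXUS splits block
#'
#' Writes a minimal NEXUS file with a taxa block and a splits block (taxon
#' indices of one side plus the isolation index as weight), the interchange
#' format understood by split-network visualization tools.
#'
#' @param splits a tibble as returned by [all_dsplits()].
#' @param labels character vector giving the taxon order used for indices.
#' @param path output file path.
#' @export
write_nexus_splits <- function(splits, labels, path) {
  lines <- c(
    "#NEXUS", "",
    "BEGIN TAXA;",
    paste0("  DIMENSIONS NTAX=", length(labels), ";"),
    "  TAXLABELS",
    paste0("    ", labels),
    "  ;",
    "END;", "",
    "BEGIN SPLITS;",
    paste0("  DIMENSIONS NTAX=", length(labels),
           " NSPLITS=", nrow(splits), ";"),
    "  FORMAT LABELS=NO WEIGHTS=YES;",
    "  MATRIX"
  )
  for (i in seq_len(nrow(splits))) {
    idx <- sort(match(splits$side_a[[i]], labels))
    lines <- c(lines, paste0("    [", i, "] ",
                             formatC(splits$alpha[i], digits = 12, format = "g"),
                             " ", paste(idx, collapse = " "), ","))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' The worked four-taxon distance matrix
#'
#' The metric 4x4 matrix over taxa `u, v, x, y` used throughout the package
#' examples: it is a metric but not additive, its minimal quartet pair-sum
#' pairs `u` with `y`, and the inverse transformation
#' \eqn{t = -10 \ln(1 - d)} makes it additive (up to the three printed
#' decimals) with the quartet flipped to `uv | xy`. Also shipped as
#' `extdata/eq3.phy` in PHYLIP format.
#'
#' @return a 4x4 [distance_matrix()].
#' @export
eq3_matrix <- function() {
  vals <- matrix(c(
    0.000, 0.503, 0.551, 0.753,
    0.503, 0.000, 0.259, 0.593,
    0.551, 0.259, 0.000, 0.551,
    0.753, 0.593, 0.551, 0.000
  ), 4, 4, byrow = TRUE)
  distance_matrix(vals, labels = c("u", "v", "x", "y"))
}
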