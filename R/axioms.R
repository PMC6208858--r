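#' Axiom checks for distance matrices
#'
#' These functions test the metric-flavoured conditions that matter for
#' distance-based phylogenetics and return tidy one-row-per-axiom reports:
#'
#' * `check_metric()` tests positivity of off-diagonal entries (M1) and the
#'   triangle inequality (M3). The zero diagonal (M0), symmetry (M2) and
#'   nonnegativity are enforced at construction by [distance_matrix()].
#' * `check_four_point()` tests the four-point condition (MA) characterizing
#'   additive (tree) metrics: for every quartet the largest of the three
#'   pair-sums exceeds the middle one by at most `tol`.
#' * `check_ultrametric()` tests the strong triangle inequality (MU): every
#'   triangle is isosceles with a short base.
#'
#' Violation magnitudes are absolute differences in distance units, so the
#' report for a matrix printed at three decimals can be interpreted at a
#' relaxed tolerance.
#'
#' @param D a [distance_matrix()] (or coercible matrix).
#' @param tol nonnegative absolute tolerance; violations of at most `tol`
#'   count as holding.
#' @return a tibble with columns `axiom`, `holds`, `worst_violation` and
#'   `witnesses` (a list column of label vectors achieving the worst
#'   violation; `NA` when there is none).
#' @examples
#' D <- distance_matrix(matrix(c(0, 1, 1, 0), 2), labels = c("a", "b"))
#' check_metric(D)
#' @export
check_metric <- function(D, tol = 1e-8) {
  D <- as_dm(D)
  lab <- dm_labels(D)
  off <- unclass(D)
  diag(off) <- Inf
  # M1 violations are zero off-diagonal entries; their magnitude is not a
  # distance excess, so worst_violation counts the offending pairs instead.
  zero_pairs <- which(off <= tol & upper.tri(off), arr.ind = TRUE)
  m1_holds <- nrow(zero_pairs) == 0
  m1_wit <- if (m1_holds) NA_character_ else lab[zero_pairs[1, ]]
  tri <- triangle_scan_cpp(unclass(D))
  m3_holds <- tri$worst <= tol
  rbind_report(
    axiom_report("M1", m1_holds, nrow(zero_pairs), m1_wit),
    axiom_report("M3", m3_holds, tri$worst,
                 if (m3_holds) NA_character_ else lab[tri$witness])
  )
}

#' @rdname check_metric
#' @export
check_four_point <- function(D, tol = 1e-8) {
  D <- as_dm(D)
  sc <- four_point_scan_cpp(unclass(D))
  holds <- sc$worst <= tol
  wit <- if (holds || anyNA(sc$witness)) NA_character_
         else dm_labels(D)[sc$witness]
  axiom_report("MA", holds, sc$worst, wit)
}

#' @rdname check_metric
#' @export
check_ultrametric <- function(D, tol = 1e-8) {
  D <- as_dm(D)
  sc <- ultrametric_scan_cpp(unclass(D))
  holds <- sc$worst <= tol
  wit <- if (holds || anyNA(sc$witness)) NA_character_
         else dm_labels(D)[sc$witness]
  axiom_report("MU", holds, sc$worst, wit)
}

axiom_report <- function(axiom, holds, worst, witnesses) {
  tibble::tibble(
    axiom = axiom,
    holds = holds,
    worst_violation = if (holds) 0 else worst,
    witnesses = list(witnesses)
  )
}

rbind_report <- function(...) do.call(rbind, list(...))

#' Quartet split relation
#'
#' For four taxa `u, v, x, y` the split relation declares `uv || xy` when
#' `d(u,v) + d(x,y)` is strictly the smallest of the three pair-sums. Ties
#' within `tol` are reported as `"unresolved"` rather than broken
#' arbitrarily, since the relation is defined by strict inequality.
#'
#' @inheritParams check_metric
#' @param u,v,x,y four distinct taxon labels present in `D`.
#' @param tol absolute tolerance below which the two smallest pair-sums count
#'   as tied.
#' @return an object of class `quadruple_call`: a list with `taxa`, `sums`
#'   (the three pair-sums, named by pairing), `topology` (one of `"uv|xy"`,
#'   `"ux|vy"`, `"uy|vx"`, `"unresolved"`) and `split` (the winning label
#'   pairing, or `NULL`).
#' @examples
#' D <- eq3_matrix()
#' quadruple(D, "u", "v", "x", "y")$topology
#' @export
quadruple <- function(D, u, v, x, y, tol = 1e-8) {
  D <- as_dm(D)
  taxa <- c(u, v, x, y)
  if (anyDuplicated(taxa)) stop("the four labels must be distinct")
  missing <- setdiff(taxa, dm_labels(D))
  if (length(missing)) stop("unknown labels: ", paste(missing, collapse = ", "))
  sums <- c(
    "uv|xy" = D[u, v] + D[x, y],
    "ux|vy" = D[u, x] + D[v, y],
    "uy|vx" = D[u, y] + D[v, x]
  )
  ord <- order(sums)
  topology <- if (sums[ord[2]] - sums[ord[1]] <= tol) "unresolved"
              else names(sums)[ord[1]]
  split <- switch(topology,
    "uv|xy" = list(c(u, v), c(x, y)),
    "ux|vy" = list(c(u, x), c(v, y)),
    "uy|vx" = list(c(u, y), c(v, x)),
    NULL
  )
  structure(list(taxa = taxa, sums = sums, topology = topology, split = split),
            class = "quadruple_call")
}

#' @export
print.quadruple_call <- function(x, ...) {
  cat("<quadruple> (", paste(x$taxa, collapse = ", "), "): ",
      x$topology, "\n", sep = "")
  print(x$sums)
  invisible(x)
}

#' Monotone consistency between two distance matrices
#'
#' Tests whether the order of distances in `D2` is consistent with the order
#' in `D1`, as required for `D2` to be a monotone transformation of `D1`:
#'
#' * mode `"m0"` (weak monotonicity): for every reference taxon `x` and taxa
#'   `y, z`, `D1(x,y) < D1(x,z)` must imply `D2(x,y) < D2(x,z)`.
#' * mode `"m1"` (strong monotonicity): `D1(x,y) < D1(u,v)` must imply
#'   `D2(x,y) < D2(u,v)` over all pairs of pairs.
#'
#' The report's `worst_violation` is the number of violating ordered
#' pairs-of-pairs; `witnesses` holds the pair-of-pairs with the largest
#' reversed margin in `D2`.
#'
#' @param D1,D2 distance matrices over the same label set.
#' @param mode `"m0"` or `"m1"`.
#' @return a one-row axiom report tibble (see [check_metric()]).
#' @export
check_monotone_consistency <- function(D1, D2, mode = c("m0", "m1")) {
  mode <- match.arg(mode)
  D1 <- as_dm(D1); D2 <- as_dm(D2)
  if (!setequal(dm_labels(D1), dm_labels(D2)))
    stop("label sets differ")
  D2 <- D2[dm_labels(D1), dm_labels(D1)]
  lab <- dm_labels(D1)
  n <- length(lab)
  pairs <- which(upper.tri(D1), arr.ind = TRUE)
  t1 <- D1[pairs]; t2 <- D2[pairs]

  n_viol <- 0L
  worst_margin <- -Inf
  wit <- NA_character_
  if (mode == "m1") {
    cmp1 <- outer(t1, t1, "<")
    bad <- cmp1 & outer(t2, t2, ">=")
    n_viol <- sum(bad)
    if (n_viol > 0) {
      margins <- outer(t2, t2, "-")  # d2(a) - d2(b), should be < 0
      margins[!bad] <- -Inf
      idx <- which(margins == max(margins), arr.ind = TRUE)[1, ]
      a <- pairs[idx[1], ]; b <- pairs[idx[2], ]
      wit <- c(lab[a], lab[b])
    }
  } else {
    for (xx in seq_len(n)) {
      others <- setdiff(seq_len(n), xx)
      for (yy in others) for (zz in others) {
        if (yy == zz) next
        if (D1[xx, yy] < D1[xx, zz] && D2[xx, yy] >= D2[xx, zz]) {
          n_viol <- n_viol + 1L
          margin <- D2[xx, yy] - D2[xx, zz]
          if (margin > worst_margin) {
            worst_margin <- margin
            wit <- lab[c(xx, yy, xx, zz)]
          }
        }
      }
    }
  }
  axiom_report(mode, n_viol == 0L, n_viol, wit)
}
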