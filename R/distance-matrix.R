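#' Labeled distance matrices
#'
#' A `distance_matrix` is a square, symmetric, nonnegative numeric matrix with
#' a zero diagonal and unique taxon labels as dimnames. Symmetry, the zero
#' diagonal and nonnegativity are validated eagerly at construction; the
#' remaining metric axioms (no zero off-diagonal entries, triangle inequality)
#' are checks, not constructor requirements, because dissimilarities arising
#' from non-injective representations are only pseudometrics.
#'
#' @param x square numeric matrix (or object coercible to one).
#' @param labels character vector of unique taxon labels; defaults to the
#'   rownames of `x`, or `t1, t2, ...` when absent.
#' @param tol nonnegative absolute tolerance used when validating symmetry and
#'   the zero diagonal. Entries within `tol` are symmetrized/zeroed exactly.
#' @return an object of class `distance_matrix` (a numeric matrix).
#' @examples
#' D <- distance_matrix(matrix(c(0, 1, 1, 0), 2), labels = c("a", "b"))
#' @export
distance_matrix <- function(x, labels = NULL, tol = 1e-8) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("distance matrix must be numeric")
  n <- nrow(x)
  if (ncol(x) != n) stop("distance matrix must be square")
  if (n < 2) stop("need at least 2 taxa")
  if (anyNA(x)) stop("distance matrix contains missing values")
  if (is.null(labels)) labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("number of labels must match matrix dimension")
  if (anyDuplicated(labels)) stop("taxon labels must be unique")
  if (max(abs(x - t(x))) > tol)
    stop("matrix is not symmetric (max asymmetry ",
         format(max(abs(x - t(x)))), " > tol)")
  if (max(abs(diag(x))) > tol)
    stop("diagonal must be zero")
  if (min(x) < -tol)
    stop("distances must be nonnegative")
  x <- (x + t(x)) / 2
  x[x < 0] <- 0
  diag(x) <- 0
  dimnames(x) <- list(labels, labels)
  class(x) <- c("distance_matrix", class(matrix()))
  x
}

#' @rdname distance_matrix
#' @export
is_distance_matrix <- function(x) inherits(x, "distance_matrix")

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", nrow(x), " taxa\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

# coerce an argument to distance_matrix, keeping it untouched if already one
as_dm <- function(x, tol = 1e-8) {
  if (is_distance_matrix(x)) x else distance_matrix(x, tol = tol)
}

dm_labels <- function(D) rownames(D)

# off-diagonal entries as a vector (each unordered pair twice)
offdiag <- function(D) D[row(D) != col(D)]

# matrix norms over off-diagonal entries; each unordered pair counted once
dm_norm <- function(M, norm = c("frobenius", "l1", "linf")) {
  norm <- match.arg(norm)
  v <- M[upper.tri(M)]
  switch(norm,
    frobenius = sqrt(sum(v^2)),
    l1 = sum(abs(v)),
    linf = max(abs(v))
  )
}

#' Read and write PHYLIP square distance matrices
#'
#' The dialect is the PHYLIP square ("lower+upper") distance-matrix format:
#' the first line holds the number of taxa, each following line a taxon label
#' and its full row of distances, whitespace-separated. Labels are free
#' strings without whitespace (the historical 10-character limit is relaxed).
#' Writing uses 12 significant digits so that write-then-read round-trips are
#' exact at that precision.
#'
#' @param path file path.
#' @param tol symmetry/diagonal tolerance passed to [distance_matrix()].
#' @return `read_phylip_dm` returns a [distance_matrix()];
#'   `write_phylip_dm` returns `path` invisibly.
#' @export
read_phylip_dm <- function(path, tol = 1e-8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a PHYLIP distance matrix: too few lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2) stop("first line must hold the number of taxa")
  if (length(lines) < n + 1)
    stop("dimension mismatch: expected ", n, " rows, found ", length(lines) - 1)
  labels <- character(n)
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != n + 1)
      stop("dimension mismatch on row ", i, ": expected ", n + 1,
           " fields, found ", length(parts))
    labels[i] <- parts[1]
    row <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(row)) stop("non-numeric distance on row ", i)
    vals[i, ] <- row
  }
  distance_matrix(vals, labels = labels, tol = tol)
}

#' @rdname read_phylip_dm
#' @param D a [distance_matrix()] (or coercible matrix).
#' @export
write_phylip_dm <- function(D, path) {
  D <- as_dm(D)
  n <- nrow(D)
  rows <- vapply(seq_len(n), function(i) {
    paste(rownames(D)[i], paste(formatC(D[i, ], digits = 12, format = "g"),
                                collapse = " "))
  }, character(1))
  writeLines(c(as.character(n), rows), path)
  invisible(path)
}

#' Read and write labeled CSV distance matrices
#'
#' The first column holds taxon labels and the header row repeats them; the
#' body is the square distance matrix.
#'
#' @inheritParams read_phylip_dm
#' @export
read_dm_csv <- function(path, tol = 1e-8) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  distance_matrix(vals, labels = labels, tol = tol)
}

#' @rdname read_dm_csv
#' @param D a [distance_matrix()] (or coercible matrix).
#' @export
write_dm_csv <- function(D, path) {
  D <- as_dm(D)
  df <- data.frame(label = rownames(D),
                   formatC(unclass(D), digits = 12, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", rownames(D))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
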