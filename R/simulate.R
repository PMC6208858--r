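#' Simulation configuration
#'
#' Collects the knobs of the data generator in one validated list. The
#' defaults are the package's reference study conditions: 100-leaf trees
#' grown by uniform leaf addition with exponential edge lengths of mean 0.05
#' substitutions per site — large enough that back-mutations matter, small
#' enough that pairwise distances stay clear of saturation — a four-letter
#' alphabet, and noise-free data (`epsilon = 0`).
#'
#' @param n_leaves number of leaves, at least 4.
#' @param topology_model `"uniform_addition"` (each new leaf attaches to a
#'   uniformly chosen edge) or `"yule"` (birth-only branching topology;
#'   edge lengths are redrawn i.i.d. in either case).
#' @param edge_length_law list: distribution name (`"exp"`, `"uniform"` or
#'   `"gamma"`) followed by its named parameters, in substitutions per site.
#' @param seed integer seed; all randomness in a generator call flows from
#'   it, so equal seeds give bit-identical output.
#' @param seq_length number of sites when sequences are simulated.
#' @param alphabet_size number of character states (default 4).
#' @param epsilon mixing weight in `[0, 1]` between the exact transformed
#'   distances and the sequence-estimated distances in [make_dataset()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 100,
                       topology_model = c("uniform_addition", "yule"),
                       edge_length_law = list("exp", mean = 0.05),
                       seed = NULL,
                       seq_length = 1000,
                       alphabet_size = 4,
                       epsilon = 0) {
  topology_model <- match.arg(topology_model)
  stopifnot(n_leaves >= 4, epsilon >= 0, epsilon <= 1,
            seq_length >= 1, alphabet_size >= 2)
  if (!is.character(edge_length_law[[1]]))
    stop("edge_length_law must start with a distribution name")
  structure(list(n_leaves = as.integer(n_leaves),
                 topology_model = topology_model,
                 edge_length_law = edge_length_law,
                 seed = seed,
                 seq_length = as.integer(seq_length),
                 alphabet_size = as.integer(alphabet_size),
                 epsilon = epsilon),
            class = "sim_config")
}

draw_edge_lengths <- function(law, n) {
  name <- law[[1]]
  p <- law[-1]
  switch(name,
    exp = rexp(n, rate = 1 / (if (!is.null(p$mean)) p$mean else 1)),
    uniform = runif(n, min = if (!is.null(p$min)) p$min else 0,
                    max = if (!is.null(p$max)) p$max else 1),
    gamma = rgamma(n, shape = if (!is.null(p$shape)) p$shape else 1,
                   rate = if (!is.null(p$rate)) p$rate else 1),
    stop("unknown edge length distribution '", name, "'")
  )
}

#' Random edge-weighted unrooted trees
#'
#' Generates a binary unrooted topology — by uniform leaf addition (each new
#' leaf subdivides a uniformly chosen edge) or as an unrooted Yule tree —
#' and assigns i.i.d. edge lengths from the configured law. Tips are
#' labelled `t1 ... tn`.
#'
#' @param cfg a [sim_config()], or an integer which is taken as `n_leaves`
#'   with the default configuration.
#' @param seed optional seed overriding `cfg$seed`.
#' @return an `ape::phylo` tree.
#' @examples
#' tr <- random_tree(sim_config(n_leaves = 8, seed = 1))
#' @export
random_tree <- function(cfg, seed = NULL) {
  if (is.numeric(cfg)) cfg <- sim_config(n_leaves = cfg)
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- cfg$n_leaves
  if (cfg$topology_model == "uniform_addition") {
    # start from the 3-leaf star; node ids: tips 1..n, internals n+1...
    edges <- rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3))
    next_internal <- n + 2
    for (leaf in seq(4, n)) {
      e <- sample.int(nrow(edges), 1)
      a <- edges[e, 1]; b <- edges[e, 2]
      w <- next_internal; next_internal <- next_internal + 1
      edges[e, ] <- c(a, w)
      edges <- rbind(edges, c(w, b), c(w, leaf))
    }
    lens <- draw_edge_lengths(cfg$edge_length_law, nrow(edges))
    tr <- build_phylo(edges, lens, n, n + 1, paste0("t", seq_len(n)))
  } else {
    tr <- ape::unroot(ape::rphylo(n, birth = 1, death = 0))
    tr$tip.label <- paste0("t", seq_len(n))
    tr$edge.length <- draw_edge_lengths(cfg$edge_length_law, nrow(tr$edge))
  }
  tr
}

sim_alphabet <- function(k) {
  if (k == 4) c("A", "C", "G", "T") else LETTERS[seq_len(k)]
}

#' Simulate sequence evolution along a tree
#'
#' Evolves aligned sequences under the symmetric k-state substitution model:
#' a first-order Markov process with equal exchange rates, uniform root
#' distribution, and edge lengths measured in expected substitutions per
#' site, so the probability of observing the parent state at the child end
#' of an edge of length `t` is \eqn{1/k + (1 - 1/k)\,e^{-k t/(k-1)}}.
#' Positions evolve independently; there are no indels and no rate
#' heterogeneity across sites.
#'
#' @param tree an `ape::phylo` tree with edge lengths in substitutions per
#'   site.
#' @param cfg a [sim_config()] supplying `seq_length`, `alphabet_size` and
#'   optionally `seed`.
#' @param seed optional seed overriding `cfg$seed`.
#' @return a character matrix of class `character_matrix` (taxa in rows,
#'   aligned sites in columns, rownames = tip labels).
#' @export
evolve_sequences <- function(tree, cfg = sim_config(n_leaves = 4),
                             seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  k <- cfg$alphabet_size
  L <- cfg$seq_length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tree <- ape::reorder.phylo(tree, "cladewise")
  root <- tree$edge[1, 1]

  states <- matrix(NA_integer_, nnode, L)
  states[root, ] <- sample.int(k, L, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    stay <- 1 / k + (1 - 1 / k) * exp(-k * t / (k - 1))
    s <- states[par, ]
    mut <- runif(L) > stay
    if (any(mut)) {
      # uniform among the k-1 other states
      shift <- sample.int(k - 1, sum(mut), replace = TRUE)
      s[mut] <- ((s[mut] - 1 + shift) %% k) + 1
    }
    states[chi, ] <- s
  }
  out <- matrix(sim_alphabet(k)[states[seq_len(ntip), , drop = FALSE]],
                ntip, L, dimnames = list(tree$tip.label, NULL))
  class(out) <- c("character_matrix", class(out))
  out
}

#' Pairwise distances from aligned sequences
#'
#' `hamming_distances()` returns the fraction of mismatched sites per pair.
#' `logdet_distances()` returns \eqn{-\ln|\det C(x,y)|} where `C(x,y)` is
#' the k-by-k matrix of fractions of sites with state `a` in `x` and state
#' `b` in `y`; on long sequences evolved along a tree this distance is
#' approximately additive. Note the log-det distance is nonzero even for
#' identical sequences (for uniform composition it equals \eqn{k \ln k}); it
#' is an additive divergence measure, not a normalized dissimilarity.
#'
#' @param M a `character_matrix` from [evolve_sequences()] (or any character
#'   matrix with taxon rownames).
#' @param on_singular for `logdet_distances`: `"error"` (default) stops when
#'   a pair's divergence matrix is singular (the distance is saturated);
#'   `"na"` returns `NA` for such pairs in a plain labeled matrix.
#' @return a [distance_matrix()] (or, with `on_singular = "na"` and singular
#'   pairs present, a plain labeled matrix).
#' @export
hamming_distances <- function(M) {
  n <- nrow(M)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    out[i, j] <- out[j, i] <- mean(M[i, ] != M[j, ])
  }
  distance_matrix(out, labels = rownames(M), tol = Inf)
}

#' @rdname hamming_distances
#' @export
logdet_distances <- function(M, on_singular = c("error", "na")) {
  on_singular <- match.arg(on_singular)
  if (ncol(M) < 1) stop("zero-length sequences: log-det undefined")
  n <- nrow(M)
  lvls <- sort(unique(as.vector(M)))
  out <- matrix(0, n, n)
  bad <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    C <- table(factor(M[i, ], levels = lvls),
               factor(M[j, ], levels = lvls)) / ncol(M)
    dt <- det(unclass(C))
    if (abs(dt) < .Machine$double.xmin) {
      bad <- c(bad, paste0(rownames(M)[i], ",", rownames(M)[j]))
      out[i, j] <- out[j, i] <- NA_real_
    } else {
      out[i, j] <- out[j, i] <- -log(abs(dt))
    }
  }
  # identical-composition diagonal analogue: d(x,x) = -ln|det C(x,x)| > 0,
  # but by convention the self-distance is 0 in the matrix representation
  if (length(bad)) {
    msg <- paste("singular divergence matrix (saturated) for pairs:",
                 paste(bad, collapse = "; "))
    if (on_singular == "error") stop(msg)
    warning(msg)
    dimnames(out) <- list(rownames(M), rownames(M))
    return(out)
  }
  distance_matrix(out, labels = rownames(M), tol = Inf)
}

#' Log-det divergence of a single pair
#'
#' Convenience accessor returning \eqn{-\ln|\det C(x,y)|} for one pair,
#' including the self-pair (which is positive: for uniform composition over
#' k states it equals `k log k`).
#'
#' @inheritParams hamming_distances
#' @param x,y taxon labels (rows of `M`); `y` defaults to `x`.
#' @export
logdet_pair <- function(M, x, y = x) {
  lvls <- sort(unique(as.vector(M)))
  C <- table(factor(M[x, ], levels = lvls),
             factor(M[y, ], levels = lvls)) / ncol(M)
  dt <- det(unclass(C))
  if (abs(dt) < .Machine$double.xmin) stop("singular divergence matrix")
  -log(abs(dt))
}

#' Generate a full synthetic dataset
#'
#' Draws a random tree, computes its additive path metric `T`, distorts it
#' entrywise to `D_theory = zeta(T)`, and, when `epsilon > 0`, mixes in
#' sequence-estimated distances: sequences are evolved along the tree,
#' Hamming distances `D_hat` computed, and the observed matrix is the convex
#' combination `D = (1 - epsilon) * D_theory + epsilon * D_hat`. Nothing is
#' clamped: the mixture can push entries to or beyond the transformation's
#' saturation level, which downstream fitting flags as infeasible rather
#' than silently clipping.
#'
#' @param cfg a [sim_config()].
#' @param z a [zeta_transform()] used as the generating distortion.
#' @return a list with `tree`, `T` (additive matrix), `D` (observed matrix),
#'   `D_theory`, `D_hat` (`NULL` when `epsilon = 0`) and `config`.
#' @examples
#' z <- zeta_transform("jukes_cantor", k = 4)
#' ds <- make_dataset(sim_config(n_leaves = 10, seed = 1), z)
#' @export
make_dataset <- function(cfg, z) {
  stopifnot(inherits(cfg, "sim_config"), inherits(z, "zeta_transform"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tree <- random_tree(cfg, seed = NA_integer_)  # NA: do not reseed below
  Tm <- tree_to_distances(tree)
  D_theory <- zeta_apply(z, Tm)
  D_hat <- NULL
  D <- D_theory
  if (cfg$epsilon > 0) {
    M <- evolve_sequences(tree, cfg, seed = NA_integer_)
    D_hat <- hamming_distances(M)
    mix <- (1 - cfg$epsilon) * unclass(D_theory) +
      cfg$epsilon * unclass(D_hat)
    D <- distance_matrix(mix, labels = dm_labels(Tm), tol = Inf)
  }
  list(tree = tree, T = Tm, D = D, D_theory = D_theory, D_hat = D_hat,
       config = cfg)
}

#' Write aligned sequences as FASTA
#'
#' @param M a `character_matrix`.
#' @param path output file path.
#' @export
write_fasta <- function(M, path) {
  lines <- character(2 * nrow(M))
  for (i in seq_len(nrow(M))) {
    lines[2 * i - 1] <- paste0(">", rownames(M)[i])
    lines[2 * i] <- paste(M[i, ], collapse = "")
  }
  writeLines(lines, path)
  invisible(path)
}
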