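#' Parametric metric-preserving transformation families
#'
#' A `zeta_transform` is a strictly increasing function
#' \eqn{\zeta: [0,\infty) \to [0,\infty)} with \eqn{\zeta(0) = 0}
#' (amenability) and an exact inverse on its range, used to model monotone
#' distortions of an additive metric. Built-in families:
#'
#' * `affine`: \eqn{\zeta(t) = \alpha t + \beta} for `t > 0`, with
#'   \eqn{\zeta(0) = 0}. For `beta > 0` the function jumps at 0; it is the
#'   exact class of transformations preserving additivity.
#' * `stretched_exp`: \eqn{\zeta(t) = a (1 - \exp(-b t^c))} with saturation
#'   level `a > 0`, rate `b > 0` and exponent `c > 0`. The range is `[0, a)`;
#'   the inverse is defined only for `d < a`.
#' * `jukes_cantor`: the sequence-evolution saturation curve for a `k`-letter
#'   alphabet, \eqn{\zeta(t) = (1 - 1/k)(1 - \exp(-k t/(k-1)))}, i.e. the
#'   stretched exponential with `a = 1 - 1/k`, `b = k/(k-1)`, `c = 1`, so
#'   that `t` is in expected substitutions per site.
#' * `neg_log`: defined by its inverse \eqn{\zeta^{-1}(d) = -s \ln(1 - d/m)}
#'   (scale `s > 0`, saturation `m > 0`); forward
#'   \eqn{\zeta(t) = m(1 - \exp(-t/s))}.
#' * `custom`: a user-supplied forward function; the inverse is computed
#'   numerically by bisection to 1e-12. Custom families need not be metric
#'   preserving — that is what [check_preserving()] is for.
#'
#' @param family family name, one of `"affine"`, `"stretched_exp"`,
#'   `"jukes_cantor"`, `"neg_log"`, `"custom"`.
#' @param ... named numeric parameters of the family (see above): `alpha`,
#'   `beta` for affine; `a`, `b`, `c` for stretched_exp; `k` for
#'   jukes_cantor; `s`, `m` for neg_log.
#' @param fn,inverse for `family = "custom"`: the forward function and,
#'   optionally, an analytic inverse; when `inverse` is `NULL` a numerical
#'   bisection inverse is used.
#' @param saturation for `family = "custom"`: the supremum of the range
#'   (defaults to `Inf`).
#' @return an object of class `zeta_transform`.
#' @examples
#' z <- zeta_transform("stretched_exp", a = 0.75, b = 4 / 3, c = 1)
#' zeta_eval(z, 0.3)
#' zeta_inverse_eval(z, zeta_eval(z, 0.3))
#' @export
zeta_transform <- function(family = c("affine", "stretched_exp",
                                      "jukes_cantor", "neg_log", "custom"),
                           ..., fn = NULL, inverse = NULL, saturation = Inf) {
  family <- match.arg(family)
  params <- list(...)
  bad <- function(msg) stop("invalid ", family, " parameters: ", msg)

  obj <- switch(family,
    affine = {
      p <- modifyList(list(alpha = 1, beta = 0), params)
      if (p$alpha <= 0 || p$beta < 0) bad("need alpha > 0, beta >= 0")
      list(
        params = p[c("alpha", "beta")],
        forward = function(t) ifelse(t > 0, p$alpha * t + p$beta, 0),
        inverse = function(d) ifelse(d > 0, (d - p$beta) / p$alpha, 0),
        saturation = Inf
      )
    },
    stretched_exp = {
      p <- modifyList(list(a = 1, b = 1, c = 1), params)
      if (p$a <= 0 || p$b <= 0 || p$c <= 0) bad("need a, b, c > 0")
      list(
        params = p[c("a", "b", "c")],
        forward = function(t) p$a * (1 - exp(-p$b * t^p$c)),
        inverse = function(d) (-log(1 - d / p$a) / p$b)^(1 / p$c),
        saturation = p$a
      )
    },
    jukes_cantor = {
      p <- modifyList(list(k = 4), params)
      if (p$k < 2) bad("need alphabet size k >= 2")
      a <- 1 - 1 / p$k
      b <- p$k / (p$k - 1)
      list(
        params = list(k = p$k),
        forward = function(t) a * (1 - exp(-b * t)),
        inverse = function(d) -log(1 - d / a) / b,
        saturation = a
      )
    },
    neg_log = {
      p <- modifyList(list(s = 1, m = 1), params)
      if (p$s <= 0 || p$m <= 0) bad("need s, m > 0")
      list(
        params = p[c("s", "m")],
        forward = function(t) p$m * (1 - exp(-t / p$s)),
        inverse = function(d) -p$s * log(1 - d / p$m),
        saturation = p$m
      )
    },
    custom = {
      if (!is.function(fn)) stop("custom family needs a forward function fn")
      inv <- if (is.function(inverse)) inverse
             else function(d) vapply(d, bisect_inverse, numeric(1), fn = fn)
      list(params = params, forward = fn, inverse = inv,
           saturation = saturation)
    }
  )
  structure(c(obj, list(family = family)), class = "zeta_transform")
}

# numerical inverse of a strictly increasing amenable function, |err| <= 1e-12
bisect_inverse <- function(d, fn) {
  if (d <= 0) return(0)
  hi <- 1
  while (fn(hi) < d) {
    hi <- hi * 2
    if (hi > 1e12) stop("value ", d, " outside the range of fn")
  }
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (fn(mid) < d) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' @export
print.zeta_transform <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), unlist(x$params), sep = "=", collapse = " ")
  else "(no parameters)"
  cat("<zeta_transform> ", x$family, " ", ps, "\n", sep = "")
  invisible(x)
}

#' Evaluate a transformation or its inverse on numbers
#'
#' `zeta_eval()` applies \eqn{\zeta}; `zeta_inverse_eval()` applies
#' \eqn{\zeta^{-1}}, signalling an error for values at or beyond the
#' saturation level where the source distance is unidentifiable.
#'
#' @param z a [zeta_transform()].
#' @param t,d numeric vectors of distances.
#' @export
zeta_eval <- function(z, t) {
  stopifnot(inherits(z, "zeta_transform"))
  if (any(t < 0)) stop("zeta is defined on nonnegative arguments")
  z$forward(t)
}

#' @rdname zeta_eval
#' @export
zeta_inverse_eval <- function(z, d) {
  stopifnot(inherits(z, "zeta_transform"))
  if (any(d < 0)) stop("inverse arguments must be nonnegative")
  if (any(d >= z$saturation))
    stop("saturated value(s) at or beyond ", z$saturation,
         ": source distance unidentifiable")
  out <- z$inverse(d)
  out[d == 0] <- 0
  out
}

#' Apply a transformation (or its inverse) entrywise to a distance matrix
#'
#' `zeta_apply()` maps every off-diagonal entry through \eqn{\zeta};
#' `zeta_invert()` maps through \eqn{\zeta^{-1}}, with an error naming the
#' first saturated pair when an entry lies at or beyond the saturation level.
#' The diagonal stays exactly zero and labels are preserved.
#'
#' @param z a [zeta_transform()].
#' @param D a [distance_matrix()] (or coercible matrix).
#' @return a [distance_matrix()].
#' @examples
#' z <- zeta_transform("neg_log", s = 10, m = 1)
#' T <- zeta_invert(z, eq3_matrix())
#' check_four_point(T, tol = 0.05)
#' @export
zeta_apply <- function(z, D) {
  D <- as_dm(D)
  out <- unclass(D)
  off <- row(out) != col(out)
  out[off] <- zeta_eval(z, out[off])
  distance_matrix(out, labels = dm_labels(D), tol = Inf)
}

#' @rdname zeta_apply
#' @export
zeta_invert <- function(z, D) {
  D <- as_dm(D)
  out <- unclass(D)
  off <- which(row(out) != col(out))
  sat <- off[out[off] >= z$saturation]
  if (length(sat)) {
    i <- arrayInd(sat[1], dim(out))
    stop("saturated entry d(", dm_labels(D)[i[1]], ", ", dm_labels(D)[i[2]],
         ") = ", out[sat[1]], " >= ", z$saturation,
         ": source distance unidentifiable")
  }
  out[off] <- zeta_inverse_eval(z, out[off])
  distance_matrix(out, labels = dm_labels(D), tol = Inf)
}

#' Numerical check of the metric-preserving properties
#'
#' Verifies on an evenly spaced grid in `[0, grid_max]` the sufficient
#' conditions for a function to be metric preserving:
#'
#' * `Z1` (amenable): \eqn{\zeta(t) = 0} iff `t = 0`;
#' * `Z2` (subadditive): \eqn{\zeta(t+u) \le \zeta(t) + \zeta(u)};
#' * `Z3` (non-decreasing along the grid);
#' * `Z*`: \eqn{\zeta(|t-u|) \le \zeta(t) + \zeta(u)}, which together with
#'   amenability is necessary and sufficient.
#'
#' This is a numerical grid check, not a symbolic proof: a function can pass
#' on the grid yet fail between grid points.
#'
#' @param z a [zeta_transform()].
#' @param grid_max upper end of the grid (distance units); defaults to 4.
#' @param grid_n number of grid points per axis (default 256).
#' @param tol absolute slack allowed in the inequalities.
#' @return a tibble with one row per property: `property`, `holds`,
#'   `worst_violation`, `witness` (list column with the worst `(t, u)` pair).
#' @examples
#' check_preserving(zeta_transform("stretched_exp", a = 0.75, b = 4/3, c = 1))
#' @export
check_preserving <- function(z, grid_max = 4, grid_n = 256, tol = 1e-10) {
  stopifnot(grid_max > 0, grid_n >= 2)
  g <- seq(0, grid_max, length.out = grid_n)
  zg <- zeta_eval(z, g)

  # Z1 on grid points: zeta(0) = 0 and zeta(t) > 0 for grid t > 0;
  # worst_violation is |zeta(0)| plus the largest non-positive excursion
  z1_bad <- (g == 0 & zg != 0) | (g > 0 & zg <= 0)
  z1_worst <- abs(zg[1]) + max(0, max(-zg[g > 0], -Inf), na.rm = TRUE)
  z1 <- list(holds = !any(z1_bad),
             worst = if (any(z1_bad)) max(z1_worst, .Machine$double.eps) else 0,
             wit = if (any(z1_bad)) c(g[which(z1_bad)[1]], NA) else c(NA, NA))

  tu <- expand.grid(t = g, u = g)
  zt <- zeta_eval(z, tu$t); zu <- zeta_eval(z, tu$u)
  v2 <- zeta_eval(z, tu$t + tu$u) - (zt + zu)
  vs <- zeta_eval(z, abs(tu$t - tu$u)) - (zt + zu)
  z2 <- worst_pair(v2, tu, tol)
  zs <- worst_pair(vs, tu, tol)

  d3 <- diff(zg)
  z3_worst <- max(0, -min(d3))
  z3 <- list(holds = z3_worst <= tol, worst = z3_worst,
             wit = if (z3_worst > tol) g[which.min(d3) + c(0, 1)] else c(NA, NA))

  tibble::tibble(
    property = c("Z1", "Z2", "Z3", "Zstar"),
    holds = c(z1$holds, z2$holds, z3$holds, zs$holds),
    worst_violation = c(z1$worst, z2$worst, z3$worst, zs$worst),
    witness = list(z1$wit, z2$wit, z3$wit, zs$wit)
  )
}

worst_pair <- function(v, tu, tol) {
  worst <- max(0, max(v))
  holds <- worst <= tol
  wit <- if (!holds) unlist(tu[which.max(v), ]) else c(NA, NA)
  list(holds = holds, worst = if (holds) 0 else worst, wit = unname(wit))
}

#' Combine feature-wise metrics
#'
#' The transformations that map additive metrics consistent with one tree to
#' a metric still compatible with that tree are exactly the sums of a
#' nonnegative linear part and nonnegative multiples of the discrete metric
#' per feature. `combine_metrics()` computes
#' \eqn{\sum_i a_i t_i + \sum_i b_i [t_i > 0]} entrywise.
#'
#' @param matrices list of distance matrices over identical label sets.
#' @param weights_linear,weights_discrete nonnegative weights `a_i`, `b_i`,
#'   one per matrix; for each feature at least one of the two must be
#'   positive.
#' @return a [distance_matrix()].
#' @export
combine_metrics <- function(matrices, weights_linear,
                            weights_discrete = rep(0, length(matrices))) {
  if (!length(matrices)) stop("need at least one matrix")
  matrices <- lapply(matrices, as_dm)
  N <- length(matrices)
  if (length(weights_linear) != N || length(weights_discrete) != N)
    stop("need one linear and one discrete weight per matrix")
  if (any(weights_linear < 0) || any(weights_discrete < 0))
    stop("weights must be nonnegative")
  if (any(weights_linear == 0 & weights_discrete == 0))
    stop("each feature needs a positive linear or discrete weight")
  lab <- dm_labels(matrices[[1]])
  out <- matrix(0, length(lab), length(lab))
  for (i in seq_len(N)) {
    Mi <- matrices[[i]]
    if (!setequal(dm_labels(Mi), lab)) stop("label sets differ")
    Mi <- unclass(Mi[lab, lab])
    out <- out + weights_linear[i] * Mi + weights_discrete[i] * (Mi > 0)
  }
  distance_matrix(out, labels = lab, tol = Inf)
}

#' Parse a plain-text transformation specification
#'
#' Specifications are a family name followed by `name=value` pairs, e.g.
#' `"stretched_exp a=0.75 b=1.0 c=1.0"`, as used by the command-line
#' interface and configuration files.
#'
#' @param spec character scalar.
#' @return a [zeta_transform()].
#' @export
parse_transform_spec <- function(spec) {
  parts <- strsplit(trimws(spec), "\\s+")[[1]]
  if (!length(parts)) stop("empty transform specification")
  family <- parts[1]
  kv <- parts[-1]
  params <- list()
  for (p in kv) {
    bits <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(bits) != 2) stop("malformed parameter '", p, "'")
    val <- suppressWarnings(as.numeric(bits[2]))
    if (is.na(val)) stop("non-numeric value in '", p, "'")
    params[[bits[1]]] <- val
  }
  do.call(zeta_transform, c(list(family = family), params))
}
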