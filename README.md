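# zetaphylo

Distance-based phylogenetics when the distance measure itself is suspect.

In molecular phylogenetics a mechanistic model of sequence evolution tells
you how to turn raw dissimilarities into evolutionary distances (the
Jukes–Cantor correction and its relatives). For many other evolving systems
— languages, manuscripts, artefacts, alignment-free sequence comparisons —
no such model exists: the measured dissimilarity `d` is at best an unknown
monotone distortion `d = ζ(t)` of an underlying additive (tree) metric `t`.
Distance methods need additivity (the four-point condition), and a nonlinear
ζ destroys it; the resulting topology errors are the distance-based analogue
of long-branch attraction. `zetaphylo` is for researchers who want to test
whether their distances can be made tree-like, and to *infer the distortion
from the data alone*.

## The core idea

Let τ be any additive-metric-consistent operator — a map taking a metric to
an additive metric while fixing additive inputs; neighbor joining is one,
the non-prime part of the Bandelt–Dress split decomposition another. For an
invertible, increasing, subadditive candidate ζ, define the non-additivity
residual

    Δ(ζ) = | D − ζ( τ( ζ⁻¹(D) ) ) |

under some matrix norm over off-diagonal entries. Then Δ(ζ) = 0 exactly when
ζ⁻¹(D) is additive, i.e. when D derives from a tree metric through ζ.
Minimizing Δ over a parametric family (the package ships affine,
stretched-exponential `ζ(t) = a(1 − e^{−b t^c})`, Jukes–Cantor saturation,
and negative-logarithmic families, plus user-defined ones) recovers both the
distortion and the approximately additive source matrix ζ⁻¹(D) — the best
available input for tree reconstruction. The rate parameter `b` only
rescales the time axis and cancels inside Δ; it is provably unidentifiable
and held fixed during fitting.

The package also provides the surrounding toolbox: metric / four-point /
ultrametric axiom checks with violation witnesses, quartet split relations,
Bandelt–Dress isolation indices and d-split enumeration, a deterministic
from-scratch neighbor joining (Rcpp), a seed-reproducible simulator (random
trees, k-state Markov sequence evolution, Hamming and log-det distances,
noise mixtures), and PHYLIP / Newick / FASTA / NEXUS-splits IO. A thin
command-line front end (`exec/zetaphylo`) exposes `simulate`, `check`,
`fit`, `tree` and `splits` subcommands.

## Worked example

The package ships a metric (but not additive) 4×4 matrix over taxa
`u, v, x, y` as `eq3_matrix()` (also `inst/extdata/eq3.phy`). Its minimal
quartet pair-sum pairs the two long branches:

```r
library(zetaphylo)
D <- eq3_matrix()
quadruple(D, "u", "v", "x", "y")
#> <quadruple> (u, v, x, y): uy|vx
#> uv|xy ux|vy uy|vx
#> 1.054 1.144 1.012
quartet_alpha(D, c("x", "v"), c("u", "y"))   # 0.066
quartet_alpha(D, c("x", "y"), c("u", "v"))   # 0.045
```

Split decomposition supports the `xv|uy` box (isolation index 0.066) over
`xy|uv` (0.045), so any additive fit of the raw distances picks the wrong
quartet. The monotone back-transform `t = −10 ln(1 − d)` repairs it:

```r
z  <- zeta_transform("neg_log", s = 10, m = 1)
Tm <- zeta_invert(z, D)
quadruple(Tm, "u", "v", "x", "y")$topology   # "uv|xy"
check_four_point(Tm, tol = 0.05)$holds       # TRUE (printed rounding only)
```

And the distortion is recoverable blindly, from the data: distort a random
100-leaf tree with the four-letter saturation curve (a = 3/4, c = 1) and
minimize Δ over the stretched-exponential grid:

```r
ds  <- make_dataset(sim_config(n_leaves = 100, seed = 1),
                    zeta_transform("jukes_cantor", k = 4))
fit <- fit_zeta(ds$D, "stretched_exp",
                grid = list(a = seq(0.5, 1, 0.025), c = seq(0.5, 1.5, 0.025)))
fit
#> <zeta_fit> family stretched_exp, nj projection, frobenius norm
#>   grid: a x 21, c x 41 points (369 saturated)
#>   argmin: a = 0.75, c = 1.00  with Delta = 9.116386e-15
autoplot(fit)   # ln(1 + Δ) surface over (a, c)
```

The argmin sits exactly at the generating parameters, with Δ at numerical
zero: the observed matrix is the image of a tree metric under the fitted ζ,
and `fit$recovered_T` is that tree metric. Grid points where an entry of `D`
would sit at or beyond the family's saturation level are infeasible
(`Δ = ∞`), never clipped. `tidy(fit)` returns the grid as a tibble,
`glance(fit)` a one-row summary.

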