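---
title: "Inferring monotone distance distortions for phylogenetic reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring monotone distance distortions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zetaphylo)
```

## The problem

Distance-based tree reconstruction rests on *additive* metrics: a metric
$t$ on a taxon set is additive exactly when it is the path-length metric of
an edge-weighted tree, which is equivalent to the four-point condition —
for every quartet, among the three pair-sums
$t(u,v)+t(x,y)$, $t(u,x)+t(v,y)$, $t(u,y)+t(v,x)$ the two largest are
equal. Outside molecular biology (and often inside it) we cannot measure
$t$; we measure some dissimilarity $d$ that we can only hope is a strictly
increasing transformation $d = \zeta(t)$ of it. Monotone, subadditive,
amenable ($\zeta(0)=0$) transformations preserve metricity, but — apart
from the affine family $\zeta(t)=\alpha t+\beta$ — they do **not** preserve
additivity, and they can even flip the quartet split relation
$uv\,\|\,xy$, the distance-based analogue of long-branch attraction. The
package's worked 4-taxon matrix (`eq3_matrix()`) is a compact example: the
raw metric supports the split $xv|uy$ (isolation index 0.066 vs 0.045),
while its back-transform under $t=-10\ln(1-d)$ is additive to printed
precision and supports $uv|xy$.

## The estimator

Let $\tau$ be an *additive-metric-consistent* operator: $\tau(D)$ is
always additive, and $\tau(D)=D$ when $D$ already is. The package provides
two: neighbor joining composed with the tree path metric (default,
consistent at any size) and the pairwise-compatible part of the
Bandelt–Dress split decomposition (exact on small taxon sets, capped at 16
taxa). For a candidate transformation $\zeta$ define

$$\Delta(\zeta) \;=\; \bigl\| D - \zeta\!\bigl(\tau(\zeta^{-1}(D))\bigr)\bigr\|$$

over off-diagonal entries. $\Delta(\zeta)=0$ **iff** $\zeta^{-1}(D)$ is
additive, i.e. iff $D$ is the $\zeta$-image of a tree metric. `fit_zeta()`
minimizes $\Delta$ over a parameter grid of a chosen family and returns the
argmin, the full residual surface, and the recovered source matrix
$\zeta^{-1}(D)$ at the argmin.

```{r worked, eval = TRUE}
D <- eq3_matrix()
c(raw = quadruple(D, "u", "v", "x", "y")$topology,
  back = quadruple(zeta_invert(zeta_transform("neg_log", s = 10, m = 1), D),
                   "u", "v", "x", "y")$topology)
```

## Transformation families and their parameters

* **affine** `(alpha, beta)` — $\zeta(t)=\alpha t+\beta$ for $t>0$,
  $\zeta(0)=0$; discontinuous at 0 when $\beta>0$. This is exactly the
  class preserving additivity, so on additive data the residual is flat in
  $\alpha$ (the scale of a tree metric is not identifiable from
  additivity alone). Default $\beta = 0$; whether a translation should be
  fitted at all is genuinely open, so it is exposed but off by default.
* **stretched_exp** `(a, b, c)` — $\zeta(t)=a(1-e^{-b t^c})$, saturation
  level $a>0$ (dissimilarity units), rate $b>0$ (per substitution), shape
  $c>0$. Range $[0, a)$: values of $d$ at or above $a$ have no preimage.
* **jukes_cantor** `(k)` — the $k$-letter sequence-saturation curve,
  $\zeta(t)=(1-1/k)\,(1-e^{-kt/(k-1)})$, i.e. `stretched_exp` with
  $a = 1-1/k$, $b = k/(k-1)$, $c = 1$, so that $t$ is in expected
  substitutions per site.
* **neg_log** `(s, m)` — defined through its inverse
  $\zeta^{-1}(d) = -s\ln(1-d/m)$; forward $\zeta(t)=m(1-e^{-t/s})$.
* **custom** — any forward function; the inverse is a bracketing bisection
  to $10^{-12}$. Custom families need not be metric preserving;
  `check_preserving()` tests amenability, subadditivity, monotonicity and
  the $\zeta(|t-u|)\le\zeta(t)+\zeta(u)$ condition on a numeric grid
  (default 256 points per axis — a check, not a proof).

**Identifiability.** The rate parameter is not estimable: replacing $b$ by
$\lambda b$ rescales $\zeta^{-1}(D)$ by $1/\lambda$, the tree projection
commutes with positive rescaling, and the forward map undoes it, so
$\Delta$ is exactly constant in $b$. `fit_zeta()` therefore never grids
over $b$ (held at `fixed$b = 1`), and `identifiability_note()` demonstrates
the cancellation numerically. The same applies to the `neg_log` scale $s$
and the affine slope on additive data. The *identifiable* parameters are
the saturation level and the shape: on the worked matrix, a grid over $m$
with $s$ fixed recovers $m = 1.0$ sharply, while a grid over $s$ is flat to
$10^{-9}$.

## Numerical choices

* **Tolerances** are explicit absolute parameters everywhere, default
  $10^{-8}$. Violation magnitudes are absolute differences because the
  axioms are stated additively; printed matrices rounded to three decimals
  need `tol` around 0.05, which is why the four-point check on the worked
  example is run at that tolerance.
* **Ties** in the quartet relation (within `tol`) return `"unresolved"`
  rather than an arbitrary winner, since the relation is defined by strict
  inequality.
* **Neighbor joining** breaks Q-criterion ties toward the smallest pair of
  node indices (tips in input label order, internal nodes in creation
  order) for cross-platform determinism. Negative branch-length estimates
  are clamped to zero with the deficit moved to the sibling edge of the
  same join — standard practice; the inputs where this matters are already
  non-additive.
* **Split decomposition** enumerates all $2^{n-1}-1$ bipartitions
  (correctness over speed; capped at $n \le 16$) and, for the projection
  $\tau$, keeps splits greedily by decreasing isolation index with a
  lexicographic tie-break, enforcing pairwise compatibility so the output
  is always a tree metric. Weakly compatible (network) splits are still
  *reported* by `all_dsplits()`.
* **Saturation** at a grid point (any entry of $D$ at or beyond the
  family's ceiling) yields $\Delta = \infty$ and a `feasible = FALSE`
  flag, never clipping — clipping would bias the argmin toward small
  saturation levels.
* **Refinement** (`refine = TRUE`) runs a derivative-free Nelder–Mead
  (Brent in one dimension) from the grid argmin at relative tolerance
  $10^{-6}$; $\Delta$ is only piecewise smooth because the projected
  topology changes discretely, so gradient methods are unsuitable.
* The $\ln(1+\Delta)$ scale in `autoplot()` is presentation only; the
  optimization always uses the raw residual. Default norm is Frobenius
  over off-diagonal entries; `l1` and `linf` are selectable because
  noise-induced bias is norm-dependent and users should be able to see
  that.

## What the simulator emulates — and what it does not

`make_dataset()` generates the package's reference study conditions:
random binary unrooted trees (uniform leaf addition; optionally Yule
topologies) with i.i.d. exponential edge lengths of mean 0.05
substitutions per site and 100 leaves by default — chosen so that
back-mutations matter but the four-letter saturation image stays below its
ceiling of 0.75 (the tests assert this calibration over seeds rather than
assume it); the exact distorted matrix $D=\zeta(T)$; and, for noise level
$\varepsilon > 0$, the convex mixture

$$D = (1-\varepsilon)\,\zeta(T) + \varepsilon\,\hat D,$$

where $\hat D$ are Hamming distances from sequences evolved site-wise
under the symmetric $k$-state Markov model (stay probability
$1/k + (1-1/k)e^{-kt/(k-1)}$ along an edge of length $t$). This mixture is
this package's construction of "measurement noise interpolating between
theory and simulation", isolated in one function so it is easy to replace;
$\varepsilon = 1$ with long sequences converges back to $\zeta(T)$. The
simulator deliberately omits indels and alignment error, rate
heterogeneity across sites, non-reversible or unequal-frequency models,
and any reticulate signal (horizontal transfer, hybridization). Passing
tests on these data therefore establish *internal consistency* of the
estimator under clean monotone distortion plus sampling noise — not
robustness on real data, where deviations from additivity are structural
as well as stochastic. `logdet_distances()` is provided as the
model-agnostic additive distance for Markov models; its four-point
violation shrinks with sequence length, which the tests check as a trend.

## Problem sizes used by the test suite

Desk-scale sizes keep the full suite near half a minute: the
Lemma-style residual characterization uses 50 random (tree, family) pairs
at 6–12 leaves; neighbor-joining consistency uses 200 trees at 4–30
leaves; split-decomposition recovery runs at 4–12 leaves; the
parameter-recovery experiment follows the reference conditions (100
leaves, grid step 0.025 in $a$ and $c$, ten seeds, nine of ten required to
land within one grid step of $a = 3/4$, $c = 1$). The heavy inner loops
(neighbor joining, path metrics, quartet scans) are in C++ so that a full
$21\times 41$ residual grid on 100 taxa takes about two seconds.

## Known limitations

* Under large noise the argmin drifts and the bias depends on the matrix
  norm; the package exposes norms and seeds for exploration but implements
  no bias correction — none is established.
* In large trees many pairwise distances crowd the tree's diameter, and
  after saturating transforms they crowd the ceiling $a$, amplifying
  noise sensitivity; entries at the ceiling are unidentifiable outright.
* `split_decomposition_tau()` discards the non-tree-like ("prime") part of
  the metric; it is the exact small-$n$ alternative, not a scalable one.
* Alternative tree-likeness objectives (statistical geometry, δ-plots) are
  out of scope; they lack the scale-cancellation property that makes
  $\Delta$ well behaved under reparameterization.
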