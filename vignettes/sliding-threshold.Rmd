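---
title: "Building co-expression networks with a sliding correlation threshold"
author: "slidenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building co-expression networks with a sliding correlation threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A gene co-expression network links genes whose expression profiles are
correlated across experimental conditions. When the expression compendium
mixes technologies and experiments, many cells of the genes × conditions
matrix are missing, and different gene pairs end up being compared over very
different numbers of shared conditions. The sample Pearson correlation
computed from `x` paired observations has a sampling standard deviation that
shrinks roughly as `1/sqrt(x)`; under the null, a pair observed together in
only 5 conditions quite easily reaches `r = 0.9`, while a pair observed in
300 conditions almost never does. A single flat correlation cutoff therefore
either floods the network with spurious low-coverage edges or discards
well-supported high-coverage ones.

## The model

slidenet computes, for every unordered gene pair, the *pairwise-complete*
Pearson correlation `r_ij` (using only conditions where both genes are
observed) together with the paired count `x_ij`. Pairs are binned by paired
count into intervals of width `binSize`; within each bin the empirical
threshold is the k-th largest correlation with `k = ceiling(cutoff *
n_pairs)` — the value a pair must reach to sit in the bin's top `cutoff`
fraction. A four-parameter curve

$$ f(x) = \alpha - \frac{1}{\eta + \lambda e^{-x/\beta}} $$

is then fitted to the per-bin points `(x_rep, q_thresh)` by bounded least
squares, and a pair becomes an edge precisely when its correlation reaches
the curve **at its own paired count**: `r_ij >= f(x_ij)`. With
`lambda >= 0`, `eta > 0`, `beta > 0` the curve is finite and non-increasing
in `x`: fewer shared conditions demand a higher correlation. `alpha - 1/eta`
is the large-`x` asymptote — the threshold applied to the best-covered
pairs — while `lambda` and `beta` control how much higher the bar is at
small `x` and how quickly it relaxes.

The construction half (`runBuild()`) and the analysis half (`runAnalyze()`)
are independent: the interchange format is a plain `Source,Target[,Weight]`
edge list, so any conforming edge list can be analysed.

## Tunable parameters

* `minPairs` (default 3): a correlation over 2 points is ±1 by
  construction, so pairs with fewer than 3 shared conditions are marked
  undefined and excluded everywhere. Undefined pairs (including
  zero-variance profiles) never enter binning or edge selection.
* `binSize` (default 10, paired-count units): narrower bins track the
  null dispersion more finely but hold fewer pairs each.
* `cutoff` (default 0.005): the retained top fraction per bin. Because the
  per-bin threshold is a rank statistic, the number of selected edges is
  close to `cutoff × n_pairs` regardless of how strong the co-expression
  signal is; `runSweep()` reports nodes/edges across cutoffs so the user
  can pick the smallest network that keeps most nodes connected.
* `minBinCount` (default 50): bins with fewer pairs give noisy extreme
  quantiles that destabilise the fit and are dropped.
* Community detection: Louvain or Leiden (modularity objective), default
  `resolution = 1`, default `seed = 42` — both heuristics are stochastic,
  and a fixed seed makes runs reproducible.
* Closeness: the default is harmonic centrality (sum of reciprocal
  shortest-path distances, unreachable pairs contributing 0), which is well
  defined on disconnected graphs; classic closeness
  (`reachable / sum of distances`, per component) is available by flag.
* Weighted analysis: edge weight is the correlation; shortest-path lengths
  use `1/weight` so strong co-expression means short distance. The k-core
  decomposition always uses the unweighted topology, since the peeling
  definition is degree-based.

## Numerical choices

* The per-bin quantile is the k-th largest value with `k = ceiling(p·n)`,
  and selection uses `>=`, so ties at the threshold are included. Only the
  signed upper tail is thresholded by default; `absolute = TRUE` switches
  to `|r|` for workflows that treat strong negative co-expression as
  evidence.
* The bin representative `x_rep` is the arithmetic midpoint of the bin's
  integer bounds (the last bin is truncated at the largest observed count).
* The curve is fitted with Levenberg–Marquardt on the residual function
  (`minpack.lm::nls.lm`) under the bounds `eta >= 1e-9`, `lambda >= 0`,
  `beta >= 1e-9`. Near-flat quantile tables leave `lambda` and `beta`
  weakly identified, so the optimiser is restarted from a fixed grid —
  `alpha0 = max(q)`, `eta0 = 1/(alpha0 - min(q) + 0.01)`,
  `lambda0 ∈ {1, 10, 100}`, `beta0 ∈ {range/10, range/3}` — and the
  smallest residual sum of squares wins. The grid is fixed, so refitting
  identical data is bit-identical. Least squares is unweighted: every
  retained bin counts equally regardless of its pair count.
* `R² = 1 - SS_res/SS_tot`; for degenerate constant tables
  (`SS_tot = 0`) it is reported as 1 when the fit is exact and 0
  otherwise. Note that on data whose per-bin quantiles are genuinely flat
  in `x`, the best attainable curve is the constant one and `R²` is near
  0 by construction — a low `R²` there reflects a flat relationship, not a
  failed fit.
* Pairwise-complete correlations are computed by a dense masked
  cross-product formulation after centring every gene by its overall
  observed mean — a per-gene constant shift that leaves each pairwise
  correlation unchanged in exact arithmetic and removes the catastrophic
  cancellation that raw-moment formulas suffer on data with large offsets.
  A pair whose restricted profile variance is below `1e-12` of its mean
  square is treated as zero-variance and marked undefined.
* Eigenvector centrality is shifted power iteration (`A + I`), computed
  per connected component with unit Euclidean norm; the shift makes the
  dominant eigenvalue strictly largest in magnitude, so the iteration also
  converges on bipartite components. Singleton components get entry 1.
* Z-scoring uses the sample standard deviation (denominator `n - 1`) over
  observed entries; columns with fewer than two observations or zero
  variance cannot be standardised and are set entirely missing with a
  warning. The transform order `removeZeros -> log2Rescale ->
  zscoreColumns` is enforced; `log2` applies no pseudocount, so
  zero-inflated data must opt into zero removal first — an explicit
  decision in favour of transparency over convenience.
* Zero removal is per cell (a zero becomes a missing value; rows and
  columns are never dropped), the most conservative reading for dropout
  handling.
* Largest-component ties are broken toward the component containing the
  lexicographically smallest node id; community ids are 0-based in
  decreasing size order, so id 0 is always the largest community.

## The synthetic generator

`generateBlockExpression()` emulates the structure the pipeline assumes:
genes split into balanced modules, gene `g` in module `m` taking
`sqrt(rho)·F_m(c) + sqrt(1-rho)·eps_gc` with standard-normal latent module
profiles and noise. This gives an expected within-module correlation of
exactly `rho` and expected between-module correlation 0, which makes test
tolerances sharp. Entries are then masked missing independently at a
configurable rate, producing the wide paired-count variation the sliding
threshold exists for. Defaults are 100 genes, 200 conditions, 4 modules,
`rho = 0.8`.

What it deliberately does **not** emulate: platform/batch effects and the
structured (technology-dependent) missingness of real compendia,
non-Gaussian expression marginals, negatively correlated modules, and
hub-like scale-free degree structure. Tests passing on this generator
demonstrate the pipeline's statistical correctness under
missing-at-random Gaussian data, not robustness to those real-data
features.

`generateNullQuantiles()` manufactures the core phenomenon directly: for
each sample size `x` it draws independent vector pairs, computes their
correlations and keeps the top-`cutoff` quantile. The resulting table is
strictly decreasing in `x` and is fitted well by the sliding-curve form
(`R² ≈ 0.98` at 20,000 replicates per `x`), which is the behaviour the
threshold corrects for.

## Problem sizes used in the checks

The test-suite studies are sized to be statistically sharp yet quick: 100
random matrices up to 30 genes for the correlation oracles, 100 random
graphs up to 25 nodes for the brute-force graph oracles (Floyd–Warshall,
iterative peeling, dense eigendecomposition), a 100-gene × 200-condition
planted study with 30% missingness for the end-to-end run, and 20,000
replicates per sample size for the null-quantile curve. The correlation
stage itself scales as `N²/2` pairs; around `N ≈ 20,000` genes is a
practical ceiling on commodity hardware.

## Known limitations

* Because the per-bin threshold is a rank statistic, edge count is pinned
  near `cutoff × n_pairs`. At small cutoffs on small gene sets this
  produces very sparse graphs (mean degree near 1) in which genuinely
  co-expressed modules fragment into several connected components;
  community partitions are then finer than the planted modules even though
  essentially all selected edges are within-module. Raising the cutoff, or
  judging recovery by edge purity rather than partition agreement, is the
  appropriate reading at that operating point.
* Pairs with undefined correlations are silently absent from the network;
  with aggressive missingness entire genes can drop out.
* Only Pearson correlation is offered; rank-based or information-theoretic
  association measures are out of scope.
* Missingness is assumed uninformative when interpreting paired counts;
  structured missingness shifts the per-bin pair populations in ways the
  threshold cannot distinguish from sampling noise.
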