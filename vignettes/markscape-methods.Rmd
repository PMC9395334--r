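---
title: "From classified rasters to marked point process statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From classified rasters to marked point process statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(markscape)
```

`markscape` implements one coherent workflow: a stack of co-registered raster
scenes of a study area is tiled into small patches, each patch is assigned a
land-cover class by a convolutional classifier (trained on a label set
enlarged by temporal label propagation), each classified patch is replaced by
a point at its center marked with its class, and the resulting marked point
pattern is analysed with second-order summary statistics against seeded null
models. This vignette explains the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the package's
synthetic benchmark does and does not demonstrate about real imagery.

## Coordinates, windows, tiling

All geometry is in **pixel units**, Cartesian with the origin at the raster's
top-left corner, x along columns and y down the rows; windows are half-open
rectangles `[0, X) × [0, Y)`. Physical scale (meters per pixel) is
deliberately kept out of the package: satellite products state it with
varying conventions, and every statistic here is invariant under a global
rescaling, so scale is at most a display factor for axis labels.

A scene of `H × W` pixels tiled with patch size `w` yields a
`floor(H/w) × floor(W/w)` grid; trailing rows and columns that do not fill a
complete patch are **dropped, not padded**, so all patches are identically
sized (as the classifier requires) and the grid stays regular (as the point
construction requires). Patches do not overlap — an overlapping tiling would
manufacture short-range structure in the point pattern that has nothing to do
with the landscape. Cell `(i, j)` (zero-based, row/column) is represented by
the center of its pixel footprint, `x = jw + w/2`, `y = iw + w/2`.

## The synthetic scene generator

Real multi-temporal archives of the kind this pipeline targets are often
access-restricted, so the package ships a first-class generator
(`generate_series()`) that emulates the *study conditions*: a fixed landscape
of `L` classes imaged `k + 1` times, each acquisition differently affected by
illumination and atmosphere.

* **Class map.** Either `voronoi` (each cell labeled by its nearest of
  `L × sites_per_class` random seed sites — compact, contiguous regions) or
  `smoothed` (a box-smoothed Gaussian field cut at its `L − 1` equally spaced
  quantiles — diffuse gradients). Real landscapes mix both morphologies;
  both generators resample a bounded number of times if a class comes out
  empty, and a grid too small to hold all classes is returned with a warning.
* **Texture.** Each `w × w` cell is drawn as its class mean color plus
  i.i.d. Gaussian noise (default within-patch sd 0.05 on the [0, 1] intensity
  scale, against between-class contrasts of order 0.2–0.5 in the default
  6-color palette). This makes the default benchmark clearly separable —
  Bayes accuracy ≈ 1 — which is intentional: it isolates pipeline defects
  from irreducible class overlap.
* **Replicates.** Each replicate applies `gain · pixels + offset + noise`
  and an optional box blur. Defaults draw the gain from ±8%, the brightness
  offset from ±0.08 and add white noise of sd 0.04 — a *moderate* level of
  inter-acquisition variation chosen as what an analyst would call realistic
  for same-season optical acquisitions; the magnitudes are free config
  parameters, not calibrated to any particular sensor. Perturbations never
  touch the class map: patch `(i, j)` has the same true label in every scene.

All randomness flows from the single config seed through per-scene derived
streams, so a series is reproducible as a whole.

What the generator does **not** emulate: spatially correlated atmospheric
effects (clouds, haze gradients), mis-registration, seasonal phenology,
mixed pixels at class boundaries, or class-dependent texture structure
(everything is i.i.d. within a patch). Tests passing on this benchmark
therefore demonstrate the correctness of the pipeline's mechanics and the
*direction* of its effects (augmentation helps under acquisition shift), not
accuracy levels transferable to real imagery.

## Temporal label propagation and leak-free splits

Because the scenes of a series are co-registered views of one landscape, a
patch labeled on the reference scene determines the label of the same cell
in every replicate. `propagate_labels()` applies exactly this: `n` labeled
cells and `k` replicates yield `n(k + 1)` labeled patches — reference
patches flagged `manual`, replicate patches `propagated` (and
classifier-labeled patches from `pseudo_label_expand()` flagged `pseudo`,
with an optional confidence floor that defaults to off, i.e. pure argmax).

The one genuinely open design point is how to split such data. Temporal
copies of a cell are near-duplicates; splitting at the patch level would put
some of them in train and their twins in test and inflate test accuracy to
near 100% regardless of the model. The package therefore assigns splits **per
grid cell**, with largest-remainder apportionment of the requested fractions
and a seeded shuffle; every temporal copy of a cell inherits the cell's
split. This is the only leak-free reading, and the construction is verified
by an explicit straddle test. Geometric augmentation (rotation/flip/scale) is
out of scope: on patch data of this kind it produces near-copies of existing
patches and is reported ineffective, so the package does not implement it.

## The patch classifier

The classifier is deliberately small. At 10 × 10 px, patches carry
large-scale color/texture information, and simple and complex architectures
are observed to perform within a couple of percent of each other on such
imagery; the package's architecture-robustness test (a 2× wider variant
moving synthetic test accuracy by < 5 points) reflects the same observation.
The layer sizes adapt the classic LeNet recipe to 10 × 10 inputs, which the
canonical 32 × 32 layout does not fit:

* conv 3 × 3, 16 filters, ReLU, 2 × 2 max-pool (10 → 8 → 4)
* conv 3 × 3, 32 filters, ReLU, 2 × 2 max-pool (4 → 2 → 1)
* dense 64, ReLU; dense L, softmax

Training protocol defaults: **Adam, batch size 256, 30 epochs, 6 classes**;
the learning rate, left open by that protocol, defaults to Adam's
conventional 1e-3 and is exposed in `classifier_spec()`. Patch intensities
are standardized per channel with training-set statistics stored in the
model. Class imbalance is handled by plain empirical risk; per-class recall
is reported in `evaluate_classifier()` so imbalance stays visible. Argmax
ties break toward the lowest class index, and top-k ranking uses the same
ordering, which makes top-k ≥ top-1 a structural identity.

The network is implemented directly in R matrix algebra (convolution as nine
shifted rank-`C` products, pooling by four-way `pmax` with first-wins
gradient routing, dense layers as BLAS products). Backpropagation is verified
against central-difference numerical gradients to 1e-4 relative tolerance in
the test suite — the strongest single check of the implementation. Geometry
is validated up front: an input too small to pass the two conv+pool stages
(or one hitting an odd size before a pool) is rejected naming the smallest
feasible patch size.

## From labels to marked point patterns

`pattern_from_labels()` puts one point at each included cell's patch center,
marked with the cell's class, in the window `[0, n_cols·w) × [0, n_rows·w)`.
The construction is exactly invertible (`floor(x/w)`, `floor(y/w)` recover
the grid), point counts equal included-cell counts, and mark probabilities
equal label shares — all tested as identities.

**The lattice artefact.** Points built this way form a perfect lattice with
spacing `w`. Nearest-neighbour statistics see maximal regularity — on the
torus the Clark–Evans index is exactly 2, since `d̄ = w` and
`λ = 1/w²` — and K̂ has a step at `r = w`. This is a property of the
construction, not of the landscape; summary functions of patch-center
patterns should be interpreted only at `r > w`, and the per-mark sub-patterns
(which are *not* full lattices) are where the ecology lives. No jitter is
applied to centers: jitter would trade a known, documented artefact for an
uncontrolled one.

## Summary statistics and their estimators

For a pattern of `n` points in a window `W` with area `|W|`, intensity
`λ = n/|W|`, the estimators are (all sums over ordered pairs `u ≠ v`,
`d_uv` the pairwise distance):

* **K-function** `K̂(r) = |W|/(n(n−1)) Σ 1(d_uv ≤ r) e(u,v)`; under CSR
  `K(r) = πr²`.
* **Cross-K** `K̂_ij(r) = |W|/(n_i n_j) Σ_{u∈i, v∈j} 1(d_uv ≤ r) e(u,v)`;
  reduces to the sub-pattern K when `i = j`, symmetric in (i, j) under
  symmetric corrections.
* **Pair correlation** `ĝ(r) = Σ k_h(d_uv − r) e(u,v) / (2πr λ̂² |W|)` with
  `λ̂² = n(n−1)/|W|²` (which makes the CSR expectation exactly 1 for the
  conditioned-on-n processes used in tests).
* **J-function** `Ĵ = (1 − Ĝ)/(1 − F̂)` with reduced-sample (border)
  corrected nearest-neighbour distribution Ĝ and empty-space function F̂
  evaluated on a ≥ 100 × 100 dummy grid; reported only where `F̂ < 1`,
  `NA` elsewhere.
* **Clark–Evans** `R = d̄_obs · 2√λ̂`, `z = (d̄_obs − 1/(2√λ̂)) / se`,
  `se = 0.26136/√(nλ̂)`, two-sided normal p-value.
* **Mark connection** `p̂_lm(r) = Σ 1(m_u = l, m_v = m) k_h(d_uv − r) /
  Σ k_h(d_uv − r)` — a ratio over ordered pairs, so values lie in [0, 1]
  and `Σ_{l,m} p̂_lm(r) = 1` by construction wherever the denominator is
  positive. Under independent marking `p_lm = p_l p_m`.
* **Mark correlation** `k̂_mm(r) = [Σ m_u m_v k_h(d_uv − r) / Σ k_h] / μ̂²`
  with `μ̂²` the mean mark product over all distinct pairs. Normalizing by
  the *pairwise* mean (rather than the squared mean of single marks) makes
  the constant-mark identity `k̂_mm ≡ 1` exact at any finite n; the
  implementation divides the pair products by `μ̂²` before the kernel sums
  so the identity holds exactly in floating point as well.

### Edge corrections, kernels, grids

* **Default correction: translation**, `e(u,v) = |W| / ((X − |dx|)(Y − |dy|))`
  — unbiased on rectangular windows and straightforward to oracle-check.
  `toroidal` (distances on the torus, unit weights) is provided mainly for
  exact tests, where it removes edge bias entirely; `none` supports oracle
  comparison and the mark statistics, whose ratio form cancels the
  correction.
* **Kernel: Epanechnikov**, `k_h(t) = 0.75/h (1 − (t/h)²)` on `|t| < h`,
  with **Stoyan's rule** `h = 0.15/√λ̂` as default bandwidth for g, p_lm and
  k_mm; the bandwidth used is always recorded on the result.
* **r grid: 512 equispaced values from 0 to a quarter of the shorter window
  side** — the conventional guard against the edge-dominated tail. `r = 0`
  is dropped (with a warning) from density-type statistics with a `1/r`
  factor; an `r` beyond half the shorter side is a validation error naming
  the bound.
* **Missing values.** Empty kernel windows, empty border denominators and
  the `F̂ = 1` tail are reported as `NA`, never interpolated.
* Ties `d_uv = r` count as inside (`≤`), matching the ball-count definition.

The reduced-sample Ĝ and F̂ are ratio estimators and not guaranteed
monotone; the monotonicity invariant is therefore asserted for K̂ (always
non-decreasing by construction) and for the uncorrected ecdf of
nearest-neighbour distances.

## Null models and Monte Carlo inference

* `simulate_poisson()` / `simulate_csr_n()` — homogeneous Poisson and its
  conditioned-on-n (binomial) variant.
* `simulate_matern_cluster()` — parents on the window **dilated by the
  cluster radius**, so the offspring process is stationary inside the
  analysis window with no artificial edge depletion; expected retained count
  `κμ|W|`.
* `simulate_ssi()` — simple sequential inhibition as the regular-process
  generator: exact, fast and sufficient for the qualitative repulsion
  regime; a Strauss sampler via MCMC would add tuning burden without
  changing what the tests need. Infeasible packings return the partial
  pattern with a warning rather than an error.
* `randomize_marks()` — permutation (exact mark multiset, fixed locations)
  or i.i.d. marks.

`envelope()` wraps any statistic in pointwise rank-based bands: under `csr`
it re-simulates conditioned on the observed n; under `random_labeling` it
permutes marks holding locations fixed. Mark statistics refuse the CSR null
(it has no marks) and unmarked statistics refuse random labeling (they would
be constant) — both are validation errors rather than silently meaningless
bands. Coverage of the rank-k band over n_sim simulations is
`1 − 2k/(n_sim + 1)` pointwise.

## Problem sizes in the test suite

The suite calibrates against closed forms at sizes chosen to make Monte
Carlo error small while keeping a laptop-scale run: 500 CSR simulations of
n = 200 for the K/g/J/Clark–Evans calibration, n = 2000 with 20 mark
randomizations for the independence limits of p_lm and k_mm, 20 seeded
fixtures of n ≤ 100 for exact oracle equivalence (tolerance 1e-10) against
naive double-loop references, a 1120-patch training set under the standard
protocol for the classifier benchmark, and 5 seeds × two training arms for
the augmentation comparison. `scripts/acceptance.R` re-runs the same
computations at 200 CSR simulations and 3 augmentation seeds.

## Known limitations

* Estimators materialize the full pairwise distance matrix: memory is
  O(n²), comfortable to n ≈ 5000, not intended for n ≫ 10⁴.
* Windows are axis-aligned rectangles only; no polygonal windows, no
  inhomogeneous-intensity variants of K or g, and no spatio-temporal
  statistics.
* The classifier is CPU-only and desk-scale by design; an alternative
  architecture can be swapped in only at the level of the spec's layer
  parameters (filters, kernel, dense width), not as arbitrary graphs.
* Pseudo-labels inherit classifier bias; the mark connection matrix of a
  classified scene differs from the truth by up to twice the
  misclassification rate (both ends of a pair can be wrong), which is
  exactly the tolerance the end-to-end test applies.
* The Clark–Evans euclidean metric carries the well-known positive edge
  bias (no Donnelly adjustment is applied); the toroidal metric is the
  recommended choice for CSR calibration and is what the package's own
  tests use.
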