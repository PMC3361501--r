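---
title: "Choosing neighborhood size by leave-one-out cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing neighborhood size by leave-one-out cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbhood)
```

## The model

The data are a census of geographic points of residence: each point $P_j$
($j = 1, \dots, n$) carries planar coordinates in meters, a count of
eligible individuals, and a count of outcome-positive individuals (vaccine
uptake being the motivating outcome).  A *filter* $N_i$ is a candidate
neighborhood definition applied around every point in turn:

* **geographic**: all individuals at points within the closed ball of
  radius $r$ meters;
* **nearly fixed population**: individuals accumulated point by point along
  the nearest-neighbor ordering until the head-count first reaches a target
  $t$; the last point may overshoot;
* **fixed population**: as above, but the last captured point contributes
  only the fraction of its individuals needed to hit $t$ exactly.

For a given filter, each point serves once as the *test set* — $p_i$ is the
outcome proportion among its own residents — while the remaining captured
individuals form the *training set* with proportion $q_i$.  The filter's
score is the leave-one-out mean squared error
$$R'_{loo}(k) = \frac{1}{n}\sum_{i=1}^n (p_i - q_i)^2,$$
and the optimal neighborhood is the size minimizing it over a grid, under
the working assumption that outcomes are more alike within a well-chosen
neighborhood than across neighborhoods.  Small filters make $q_i$ noisy
(few training individuals); large ones make it biased (they average over
genuinely different areas); the MSE trades the two off.

This is a scale-selection device, not an inference procedure: no standard
errors, no spatial model.  It assumes coordinates are already projected to
planar meters (the package does no geodesic math) and applies no edge
correction at the study-area boundary, so border points see truncated
neighborhoods — a known bias shared by the plain method.

## Decisions in corners the definition leaves open

* **Ball boundary.** "Within radius $r$" is read as the closed ball
  ($d \le r$), the conventional reading.
* **Distance ties.** The nearest-neighbor ordering breaks ties by ascending
  point id (byte order).  Co-located points are legal and rank immediately
  after the center.  Any tie rule would do statistically; a fixed one makes
  every capture bit-reproducible.
* **Does the center count toward the population target?**  The accumulation
  starts at the center point, so by default its residents count toward the
  target (`target_includes_center = TRUE`).  The alternative reading —
  accumulate only training individuals — is available as
  `target_includes_center = FALSE`; with the fixed-population kind the
  weighted *training* head-count then equals the target.
* **Centers with no training data.**  A center whose filter captures nobody
  else (isolated dwelling under a small radius; a center meeting the
  population target alone) has no defined $q_i$.  Such records are excluded
  from numerator *and* denominator ($\mathrm{MSE} = \sum/n_{included}$),
  rather than zero-filled, which would silently reward filters that strand
  points.  `n_excluded` is always reported, and an entry excluding more
  than 5% of centers carries a warning: its MSE is not comparable with its
  neighbors' on the curve.
* **Fractional positives.**  Under the fixed-population kind the last
  point's positives enter at expected value ($w \cdot \mathrm{positives}$),
  not by random subsampling; the estimate stays deterministic.  The
  center/test point is never fractionated.
* **Unreachable targets.**  A population target exceeding the total
  head-count captures the whole set flagged `target_unreached` and is
  excluded, mirroring the empty-training rule (for the fixed-population
  kind this is an error at the single-capture interface, where the
  precondition is explicit).

## Size grids

Defaults follow the two-regime convention: fine steps where the MSE curve
moves quickly, coarse steps beyond — 50–200 m by 50 m then 400–2,000 m by
200 m for the geographic filter (`geographic_grid()`; a dense 10–200 m by
10 m lower regime via `dense = TRUE` for very dense sites where the optimum
can sit below 50 m), and 50–200 by 50 then 400–6,000 by 200 persons for the
population filter (`population_grid()`).  Grids are sweeps of independent
entries; `sweep_filters()` resolves all sizes from one sorted neighbor
profile per center ($O(n^2 \log n + nk)$ instead of the naive
$O(n^2 k)$), and the test suite pins the swept path to a naive per-capture
reference at $10^{-12}$.

## Density CV and heterogeneity

Local density at a point is the head-count within the closed ball over the
ball area $\pi r^2$, reported in persons per hectare.  Its coefficient of
variation across points, averaged over a 10–200 m by 10 m radius grid,
classifies the site: mean CV in $[0, 0.5)$ homogeneous, $[0.5, 0.7)$
moderately homogeneous, $[0.7, \infty)$ heterogeneous.  The boundary values
are assigned upward to make the map total.  The CV uses the population
standard deviation (divisor $n$): the point set is the full census of the
area, not a sample (`sd_type = "sample"` switches).  The profile's `std_cv`
is the sample sd of the per-radius CVs, a descriptive spread of the curve.
The constant $\pi r^2 / 10^4$ cancels in sd/mean, so the CV depends only on
captured head-counts; scaling every population by a constant leaves it
unchanged.

## What the simulator emulates — and what it does not

`simulate_points()` generates homogeneous Poisson patterns (points uniform,
count Poisson at the stated intensity) or Thomas cluster processes (parents
plus isotropic Gaussian offspring, sd = `cluster_radius`; offspring outside
the window are redrawn rather than clipped so the window intensity stays
interpretable).  Household sizes are constant or $1 + \mathrm{Poisson}(\mu)$
— every mapped point houses at least one eligible individual.  Outcomes are
independent Bernoulli individuals with a coverage probability that is
global, per-cluster, or a smooth surface $p(x, y)$.

Three scenarios span the regimes the method must distinguish:

* **S1 (cluster recovery)**: 20 clusters on a 5 × 4 grid of parents 500 m
  apart, sd 30 m, mean 20 points per cluster, households
  $1 + \mathrm{Poisson}(4)$, cluster coverage alternating 0.2/0.8.  The
  generative truth is known, so the selected radius can be judged: it
  should exceed about twice the cluster scale (≈ 60 m, covering the own
  cluster) and stay well short of the 500 m gap.  Across seeds the sweep
  selects radii around 80–200 m.
* **S2 (homogeneous)**: Poisson, intensity 0.01 points/m² in a 1 km²
  window (about 10,000 single-person points) — expected ball counts
  $\pi r^2 \lambda$ are large at all grid radii, so the density CV is small
  and the site classifies homogeneous.
* **S3 (heterogeneous)**: 10 tight clusters (sd 20 m) in a 2 × 2 km
  window, empty elsewhere, households $1 + \mathrm{Poisson}(4)$.  Cluster
  sizes are deliberately unequal: one dominant settlement (mean 150 points)
  and nine small pockets (mean 15).  The contrast matters: at radii beyond
  ≈ 70 m each ball holds exactly its own cluster, so the CV plateaus at the
  *point-weighted* between-cluster head-count CV, and for equally sized
  clusters that plateau is only the small Poisson between-cluster
  variation.  The point-weighted CV of a one-large/many-small composition
  is maximized when the large cluster holds roughly ten times the small
  ones' head-count — the configuration chosen here, which mirrors the
  order-of-magnitude contrasts between a main settlement and outlying
  pockets in real heterogeneous sites and keeps the mean CV in the
  heterogeneous band across seeds.

What passing these scenarios does *not* show: real censuses have
within-point household mixtures, boundary effects against roads and water,
spatially autocorrelated coverage beyond cluster labels or smooth ramps,
and recording error in coordinates.  Results on the scenarios demonstrate
that the machinery recovers known structure, not that any particular field
site has a 110 m neighborhood.

All generation is seed-driven; the pattern and the outcome assignment use
separate streams derived from the one seed, so each is independently
reproducible.

## Numerical contract

Accumulations use R's long-double summation, keeping the swept path equal
to the naive reference at $10^{-12}$ even at $n = 10^4$.  Machine-readable
outputs (CSV/JSON from `run_pipeline()`) serialize numbers at 12
significant digits; identical input and configuration give byte-identical
files.  The cell-binned neighbor scan used for large point sets (cells of
side $\max(r)$, 3 × 3 neighborhoods) is exact, not approximate, and the
tests assert bit-equality with the dense scan.

The evaluation sizes used throughout the test suite — oracle equivalence at
$n \le 200$ over the full default grids, 20-replicate recovery and
classification runs at $n \approx 300$–$10^4$ — were chosen so the whole
suite exercises every path at full strength while remaining a desk-scale
computation.

## Limitations

* No boundary correction: CV is biased upward and captured populations
  downward for points near the window edge.
* The MSE curve is evaluated pointwise on the grid; no interpolation
  between grid sizes is attempted, so the reported optimum is grid-resolved
  (ties break toward the smaller size).
* Euclidean planar distance only: project first, and do not use the package
  across map-projection seams.
* The method scores aggregation scales; it does not model the outcome.
  Downstream analyses (e.g. neighborhood-level coverage in effectiveness
  models) inherit the usual ecological-inference caveats.
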