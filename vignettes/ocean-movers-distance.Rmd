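---
title: "Methods: optimal-transport distances for ocean scalar fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal-transport distances for ocean scalar fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceanmover)
```

## The model

A gridded non-negative field (chlorophyll-a concentration, or any tracer) is
normalized by its total over the valid cells, turning it into a discrete
probability distribution `P` on the grid. Two such distributions `P`, `Q`
are compared through the transportation linear program

$$\hat f = \arg\min_f \sum_{i,j} f_{ij}\, d_{ij}^2
\quad\text{s.t.}\quad f_{ij}\ge 0,\;\; \sum_j f_{ij}=P_i,\;\; \sum_i f_{ij}=Q_j,$$

whose square-rooted optimum is the 2-Wasserstein distance
$W_2(P,Q)=\big(\sum_{ij}\hat f_{ij} d_{ij}^2\big)^{1/2}$. The base distance
$d_{ij}$ is physical: great-circle kilometres between cell centres for maps
(Euclidean distance is not adequate at basin scale), absolute depth
difference in metres for vertical profiles. $W_2$ therefore carries
spatial units, is a metric on distributions over a common support, and the
optimal plan $\hat f$ — which conserves mass by construction — doubles as a
visualization of *how* the two fields differ. The plan is not physical
advection: it is the cheapest bookkeeping that morphs one normalized field
into the other.

Assumptions worth keeping in mind:

* normalization discards the total mass; two fields differing only by a
  multiplicative constant are at distance zero (by design — the method asks
  about patterns, not magnitudes; RMSE is provided as the complementary
  magnitude-sensitive measure);
* both inputs must be non-negative with positive total;
* the quadratic cost makes long moves expensive and composite ("relayed")
  moves cheap, so in the presence of a large common background the optimal
  cost of displacing a feature grows sublinearly until the background's
  relay capacity is exhausted (see the toy experiment below).

## Solver

`solve_transport()` is an exact transportation (network) simplex over the
bipartite spanning-tree basis, in C++:

* **Initialization** is Vogel's approximation (largest row/column penalty
  first) with cached two-smallest entries per line, completed to a spanning
  tree with zero-mass arcs when allocations leave the basis short.
* **Pivoting** selects the most negative reduced cost; the entering-arc
  tolerance is `1e-11 * max(cost)`, i.e. well below any physically
  meaningful cost difference but above accumulated floating-point noise in
  the tree potentials.
* **Degeneracy.** No numerical perturbation of the supplies is applied: a
  perturbation of size $\delta$ leaks $O(\sqrt{m\delta})\cdot d$ into
  $W_2$ after the square root, which would destroy exact zeros
  ($W_2(P,P)=0$) and the `1e-10`-level symmetry the tests assert. Instead,
  leaving-arc ties are broken lexicographically and, after a run of
  zero-length pivots longer than $m+n$, the entering rule falls back to
  Bland's rule, which precludes cycling.
* **Zero-probability cells** are dropped from the support before solving
  (cannot change the optimum); arc indices are mapped back afterwards.
* **Forbidden arcs** (`Inf` base distances from `mask_long_arcs()`) become
  big-M costs; if any big-M arc carries mass above `1e-9` at the optimum the
  problem is reported infeasible (`omd_infeasible_error`).
* **Marginal tolerance.** Inputs must sum to 1 within `1e-9` (error
  otherwise: "unbalanced masses") and are renormalized once, with a message
  when the adjustment exceeds `1e-12`.

Two independent oracles guard the solver: a generic dense two-phase tableau
simplex on the identical LP (`solve_transport_lp_oracle()`, for small
instances), and the closed-form quantile representation of 1-D $W_2$
(`wasserstein_1d()`) for profiles. The test suite asserts agreement at
`1e-9` (objective, unit-scale costs) and `1e-8` ($W_2$, metres).

## Downstream analyses

**Distance matrices and MDS.** `pairwise_distance_matrix()` computes the
$N(N-1)/2$ unique pairs and mirrors them. `classical_mds()` embeds the
matrix via the eigendecomposition of the doubly centred squared-distance
matrix (`stats::cmdscale` does the decomposition). Wasserstein matrices
need not be Euclidean-embeddable, so negative eigenvalues are clamped to
zero — the standard classical-MDS convention; if fewer than `dim`
eigenvalues are positive the missing coordinates are zero-padded with a
warning. Orientation is arbitrary in principle, so a deterministic sign
convention (largest-magnitude coordinate of each axis positive) is applied,
and tests compare embedded *distances*, never raw coordinates. $W_2$ (not
$W_2^2$) is used as the dissimilarity, matching the definition of the
matrix; the function accepts any symmetric matrix if a user prefers squared
input.

**Seasonal-trend regression.** For maps dated (year, month), the distance
between maps $a$ and $b$ is modelled as
$\beta_0+\beta_1\,|ym(a)-ym(b)| + \sum_{k=0}^{6}\beta_{2,k}\,
\mathbf 1(|m(a)-m(b)|=k)$ with $\sum_k\beta_{2,k}=0$; the calendar lag is
the circular month distance folded to $\{0,\dots,6\}$. The constraint is
imposed through a sum-to-zero reparameterization and the model fitted by
ordinary least squares on all upper-triangle pairs. Design choices:

* pairs are treated as independent observations, as is conventional for this
  regression; the standard errors do not correct for the dependence among
  pairs sharing a map (documented caveat);
* the response is the raw $W_2$;
* calendar lags 0 and 6 occur half as often as 1–5 on the circle; no
  reweighting is applied (plain OLS);
* when some calendar-lag levels are absent, the constraint is applied over
  the levels present and absent levels get coefficient zero (recorded in
  `$absent_lags`); fewer than two levels, or a design made collinear by the
  date pattern, is an error naming the missing lags.

`slope_ratio()` compares the $\beta_1$ of two sources (e.g. satellite vs
model); a zero denominator yields `NA` with a warning, a negative one flips
the sign with a warning.

**Provinces.** `kmeans_provinces()` clusters the raw per-cell values (a 1-D
feature — the front of interest is a value front, so coordinates are not
used as features; `log10_values = TRUE` is available since chlorophyll is
log-distributed in nature) with seeded K-means, 10 restarts, and labels
renumbered by increasing cluster mean so the labelling is deterministic.
`boundary_field()` marks every valid cell with a 4-neighbour of a different
label — both sides of the interface, making the boundary invariant to
relabelling — and puts uniform mass on the boundary cells. 4-connectivity is
the simplest discretization; 8-connectivity would thicken diagonal
boundaries. `boundary_distance()` composes clustering, boundary extraction
and transport, so province boundaries from two data sources can agree even
when the underlying fields disagree in magnitude.

**Depth profiles.** The deep chlorophyll maximum (DCM) is the argmax depth
of the profile (invariant to normalization); ties break to the shallowest
depth. `colocalize()` averages model records within ±2 days and ±5 m
(inclusive bounds, unweighted arithmetic mean) of each in-situ sample;
samples with no record in the window are dropped and reported.
`profile_from_samples()` assigns samples to the nearest axis depth (ties
shallower), averages within a bin — concentration is intensive, so the bin
mean, not the sum, is the right aggregate — and normalizes.
`dcm_regression()` regresses both $W_2$ and RMSE on the (absolute, by
default) DCM difference and reports the two $R^2$; the absolute difference
is used because the distances themselves are unsigned.

## Synthetic study conditions

The generator exists so that every stage is testable without external data.
Its defaults were fixed once, as follows, and the tests and
`scripts/acceptance.R` run on them:

* **Toy patch experiment** (`patch_distance_curve()`): 2.5° grid over
  longitude −180…−100, latitude −30…10; logistic background front
  (0.05 to 1 mg m⁻³, width 5°) centred at 5°N so the patch region lies on
  the low plateau, emulating a transition-zone front north of an
  oligotrophic gyre; circular Gaussian patch (amplitude 1 mg m⁻³,
  σ = 550 km, rotation available but off by default) at (−150, −15), shifted
  east by 0–40° in 5° steps. Patch supports effectively disjoin near a 20°
  shift (≈ 4σ), beyond which RMSE is flat while $W_2$ keeps growing. The
  patch must sit on a *low* background: with a comparable background under
  the path, quadratic-cost relays bend the $W_2$-vs-shift curve visibly.
* **Seasonal series** (`make_seasonal_series()`): a Gaussian blob
  (σ = 400 km) whose centre longitude follows an annual sinusoid
  (default amplitude 800 km) plus linear drift and seeded jitter, on a flat
  or frontal background; drift-recovery checks keep the monthly
  displacement at or above the cell size, because $W_2$ between discretized
  near-translates scales like the square root of sub-cell displacements.
* **Profiles** (`make_profile()`): Gaussian peak over a small surface
  baseline on a 0–200 m axis, peaks near 96 m ("in-situ-like") and 140 m
  ("model-like") in the pooled-transport checks; `shift_profile()` produces
  exact discrete translates, for which $W_2$ equals the shift exactly.

All generators are deterministic given their seed (the RNG state of the
caller is left untouched). What the generator does **not** emulate: realistic
spatial spectra or cloud-mask geometry of satellite products, correlated
observation noise, multi-feature fields. Passing tests therefore demonstrate
the correctness and the qualitative contrasts of the machinery, not
performance on real satellite or model data.

## Problem sizes and numerics

The shipped experiments use grids of a few hundred cells (the patch
experiment: 561 cells, eight transport solves) and profile axes of 41–51
depths; the C++ solver handles these exactly in seconds. Cost matrices are
dense, so memory grows as $m\times n$; for much larger grids the
`mask_long_arcs()` local-transport variant reduces the effective arc set but
the matrix itself remains dense — a genuine limitation of this
implementation.

Numerical conventions collected in one place: probability sums are enforced
to `1e-9` and reported plans conserve marginals to better than `1e-10`;
entering tolerance `1e-11·max cost`; big-M is `1e7·(max finite cost + 1)`;
plan masses below `1e-13` are dropped as rounding dust; CSV output uses 17
significant digits so write→read round-trips are exact; K-means uses 10
restarts with a fixed seed; MDS eigenvalue positivity threshold is
`1e-12·λ₁`.

## Known limitations

* Normalization discards total mass; unbalanced transport is out of scope.
* Base distances are spherical (IUGG mean radius 6371.0088 km, haversine);
  ellipsoidal corrections (~0.3%) are far below the grid resolutions used,
  and sphericity keeps the metric exactly symmetric. Land-avoiding or
  current-aware base distances are not implemented.
* When several optimal plans exist, the arc set returned (and drawn) is the
  particular basic solution the simplex terminates at; the objective and
  $W_2$ are unique, the arrows need not be.
* NetCDF ingestion is not provided; fields are exchanged as lon/lat/value
  CSV.
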