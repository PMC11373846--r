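---
title: "Methods: simulating habitat use from individual step-selection models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating habitat use from individual step-selection models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepscape)
```

## The problem and the model

When a population is expected to recolonize — or be reintroduced into —
a landscape it does not currently occupy, managers need predictions of
where use will concentrate before any local data exist. `stepscape`
addresses this by projecting movement models fitted *elsewhere* (on a
donor population) onto the target landscape and simulating where
individual animals would take their steps.

Each individual model is an integrated step-selection function (iSSF)
with exponential form `w(x) = exp(x'β)` over seven habitat covariates at
300-m resolution: NDVI (a food-abundance index in [0, 1]), terrain
ruggedness, distance to forest edge (m), densities of forest edge,
riparian areas and buildings (per unit area), and distance to secure
habitat (m). Fitting the iSSFs (conditional logistic regression on
telemetry, per-individual model selection) is upstream of this package;
coefficients arrive as data, with dropped terms encoded as exact zeros.
Because the upstream covariate scaling is not knowable from the
coefficients alone, covariates are used exactly as supplied and the
coefficients are assumed to be on that scale — there is no internal
standardization.

### Conductance surfaces

An individual's conductance surface is `exp(β·x_i)` per cell `i`,
winsorized at the 0.025 and 0.975 quantiles of the in-area values and
min–max rescaled to [0, 1]. Two deliberate choices:

* **Winsorize, don't drop.** Trimming extremes by *removal* would leave
  cells without a movement weight; clamping to the quantile values
  preserves full spatial support while still preventing a handful of
  extreme cells from dominating the weighting. Ranks strictly inside the
  clamp bounds are preserved.
* **Numerics.** The linear predictor is shifted by its maximum before
  exponentiation. The shift cancels in the min–max normalization (the
  surface is provably invariant to adding any constant to the
  predictor), and it prevents floating-point overflow for large
  coefficient-covariate products. A constant post-clamp surface
  normalizes to all-1 (uniform movement) rather than all-0, so movement
  remains defined.

Quantiles here and everywhere else in the package use linear
interpolation between order statistics (R's default type 7), computed
over simulation-area cells only.

### Movement simulation

Movement is a conductance-filtered correlated random walk. Per step, 11
candidate steps are drawn — lengths from the individual's gamma
distribution, turns from its von Mises distribution centered on zero —
and one candidate is chosen with probability proportional to the
conductance value at its endpoint cell (no along-path averaging). The
gamma/von Mises forms are the standard parameterization of the empirical
step-length and turn-angle distributions in step-selection analyses; the
von Mises sampler is the Best–Fisher (1979) rejection algorithm,
implemented in-package and checked against circular-moment identities.
The initial heading is uniform on [0, 2π).

Candidates landing off the grid or outside the simulation area get
weight zero. If an entire candidate set has zero weight, the set is
redrawn up to `boundary_retry_limit` (default 100) times; if still no
valid candidate exists the animal *stalls*: the current location is
recorded again as that step's endpoint. This keeps every endpoint on the
mapped surface and conserves step counts exactly
(Σ counts = iterations × n_steps, always). The buffer-style simulation
area around the study area makes stalls rare in realistic geometries;
the stall counter is reported per bear so heavy stalling is visible.

An iteration is 20,000 steps; a scenario runs 100 iterations per female
and 242 per male model, so the default 46-female/19-male population
yields 4,600 and 4,598 iterations — near-equal per-sex totals. Each
iteration's RNG stream is seeded deterministically from
`(base_seed, bear id, iteration index)`, making results bit-reproducible
and independent of execution order. Only step endpoints deposit counts;
the start location itself does not (the step, not the site, is the unit
of use).

Start locations: the *recolonization* scenario samples uniform random
points in a start buffer (default 25,000, thinned to ≥ 10 m pairwise
spacing by rejection in insertion order), keeps those whose cell falls
in the top 3 classes of a prior connectivity map, and drops points in an
exclusion mask (e.g. city boundaries); the *reintroduction* scenario
draws uniform random points inside the release-zone mask.

### Maps, validation, and summaries

Step-count rasters are binned within the study area into 10 quantile
classes (breaks at the 0.1 … 0.9 quantiles; class = 1 + number of breaks
*strictly below* the value, so ties go to the lower class). With
all-distinct values every class holds 10% of cells (±1 cell); with the
heavy zero-ties of short runs, lower classes absorb the surplus — a
documented property, asserted only for distinct inputs. This tie rule is
deterministic, order-independent, and invariant under strictly
increasing transforms of the counts. Each map product (per sex, per
scenario, per sequence window, combined) is binned independently with
its own breaks. Sequence maps split each iteration's step indices into
four consecutive equal windows (steps 1–5,000, 5,001–10,000, … at the
default length); window rasters sum exactly to the total.

Validation overlays point locations on a class map and reports the
Spearman rank correlation between class values 1–10 and per-class
location counts (average ranks for ties; undefined — `NA` — for
zero-variance counts), the mean class, and the percentages in the top
class and in classes 6–10 ("top half"; with class 10 as "the top class",
the top 5 of 10 classes). Points outside the study area are excluded
and counted, not errors. Spearman is computed on the 10 (class, count)
pairs, not per point, matching the class-occupancy formulation.

Habitat summaries report, per region, the median, interquartile range
and 95% range of each covariate; per class, the arithmetic mean of each
covariate (a rising profile across classes indicates selection for that
covariate); and per class, the proportion of use by land-ownership
category. Ownership proportions are **step-weighted** by default —
"use" means steps taken, so a cell visited often counts more — with a
cell-area-weighted variant exposed as an option (`weight = "area"`);
which variant an upstream analysis intends is rarely stated, so both
are available.

## The synthetic-data generator

The generator exists so every stage is testable end to end without
external data. It emulates the *statistical structure* the analysis
assumes, not any real geography:

* **Covariates** are Gaussian random fields — white noise smoothed with
  a separable Gaussian kernel to a configurable autocorrelation range
  (default 3,000 m = 10 cells), then transformed monotonically to the
  target range (logistic for NDVI, exponential quantile transform for
  distances/densities, log-normal-style for ruggedness). Kernel
  smoothing was chosen over variogram simulation as simpler and
  sufficient: the movement weighting needs spatial coherence, not a
  specific covariance family.
* **Geometry**: a rectangular study area inset in a buffered simulation
  area (margin ≥ 1 cell, so containment is strict); a central recovery
  zone split into North/Central/South thirds; a northern edge band as
  the recolonization start buffer with a small exclusion block; three
  ownership categories from terciles of another smoothed field. Default
  grid 200 × 200 cells (60 × 60 km), chosen so full test suites run in
  minutes.
* **Population**: default 46 females + 19 males. Mean coefficients are
  signed as the donor-population analyses report selection (positive
  NDVI, forest-edge density, riparian density; negative ruggedness,
  building density, and both distances), with between-individual SD of
  30% of |mean| and a 0.2 probability of zeroing any term (emulating
  per-individual model selection). Movement kernels for 3-hour steps:
  mean step length uniform in 500–1,500 m (females) or 800–2,000 m
  (males), gamma shape in 0.8–2, von Mises κ in 0.2–1 — order-of-
  magnitude choices for bear-scale movement, all config-exposed, since
  the per-individual kernel parameters of the motivating analysis are
  not published at this granularity.
* **Prior class map** (for start-node filtering): quantile classes of a
  smoothed random field over the simulation area — a *synthetic*
  stand-in carrying no real connectivity information. Where it feeds
  the narrow start buffer, a short correlation range (~2 cells) is used
  so top classes speckle across the whole area and the buffer always
  contains eligible nodes; long-range fields can otherwise leave a thin
  buffer entirely outside the top classes.
* **Validation points** sample study-area cells with probability ∝
  class^γ (uniform within the cell). On a balanced map the mean class
  has closed forms — 5.5 at γ = 0, Σc²/Σc = 7.0 at γ = 1 — used as
  recovery oracles in the tests.

What passing tests on synthetic data do *not* show: transferability of
real fitted coefficients to a real target landscape, realism of any
particular geography (highways, valleys, river networks), or behavioral
processes the walk omits (below).

## Problem sizes and tolerances

Tests and the acceptance script run scaled-down designs — typically
50–80-cell grids, 2–10 bears, 5–20 iterations of 200–1,000 steps, with
one full-length 20,000-step iteration to verify the sequence-window
arithmetic — sizes chosen so the whole suite completes in a few minutes
while still exercising every code path at meaningful Monte-Carlo
precision. Stochastic assertions use explicit error bands: exact
binomial or chi-square bounds for frequencies, 3-standard-error bands
for means, and 1e-12 for deterministic numerical identities.

## Known limitations

* Simulated animals do not die, rest, hibernate, or establish home
  ranges, and there is no interaction among individuals; the maps are
  relative-use predictions under sustained exploratory movement, not
  demographic forecasts or timelines.
* The stall-in-place boundary rule is this package's declared policy;
  with a generous simulation-area buffer it triggers rarely, but very
  tight geometries will inflate counts at the boundary cells where the
  animal is trapped.
* Whether use should be tallied as endpoint counts or as rasterized
  line traversals is a modelling choice; endpoints are used here.
* With zero-inflated short runs the equal-area property of class maps
  is intentionally violated by the ties-to-lower rule; compare class
  areas before interpreting per-class statistics from short runs.
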