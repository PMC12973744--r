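---
title: "Methods: suitability, density and spatial association in predscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suitability, density and spatial association in predscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predscape)
```

predscape chains four stages of a spatial predator--prey analysis:
occurrence processing, habitat-suitability modelling, camera-trap density
estimation, and spatial-association statistics. This vignette explains the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data module does and does not emulate.

## Rasters and coordinate handling

All gridded data travel as `raster_grid` objects: a value matrix (row 1 =
north), an origin, a square cell size in meters, and a CRS tag. Records
are required to already be in a projected CRS in meters (the package was
designed around UTM zone 33N); coordinates are validated against the
declared extent but never reprojected. Raster I/O uses the ESRI ASCII grid
format — a plain-text interchange format that any GIS reads — with `NA`
round-tripped through the `NODATA_value` sentinel.

Cell membership is half-open, $[x_0, x_0 + c) \times [y_0, y_0 + c)$, with
points on the maximum edge of the extent clamped into the last cell, so
every point of the closed extent belongs to exactly one cell. Bilinear
resampling in `align_rasters()` interpolates cell-center values;
coordinates beyond the outermost cell centers are clamped to the
center hull, which preserves constant rasters exactly, and any stencil
touching `NA` yields `NA`. Distances in `distance_to_class()` are
center-to-center Euclidean: raster resolution does not support a finer
edge-to-edge notion. Slope and aspect use the standard Horn 3x3 stencil;
aspect is the downslope direction and is undefined (NA) on flat cells.

## Occurrence processing

Multi-source presence records (surveys, camera traps, roadkill, citizen
science) carry species, projected coordinates, date, source and a count of
individuals. Two cleaning rules are applied in order:

1. **Deduplication** removes records sharing species, coordinates *and*
   date; the same place on different dates is a repeat observation, not a
   duplicate.
2. **Spatial thinning** enforces at most one record per species per grid
   cell, the standard mitigation of spatial clustering and observer bias
   in presence-only modelling. The grid resolution is a parameter,
   defaulting to the predictor cell size (100 m). Where several records
   compete for a cell the earliest date wins, with ties broken by input
   order — an arbitrary but deterministic and auditable rule; the
   reference workflow this emulates does not specify one.

Both operations are idempotent and order-stable, and rows rejected at any
stage (unparseable fields, points off the grid) are tallied in a rejection
report rather than raised as errors, so bulk field data loads cleanly.

## Predictor screening

Collinear predictors destabilize weight estimates, so the stack is
screened before modelling. `vif_filter()` computes, over a seeded
subsample of complete cells (default 10,000, matching common practice for
rasters of this size), the variance inflation factor
$\mathrm{VIF}_j = 1/(1 - R^2_j)$ of each layer regressed on the retained
others, and iteratively removes the worst layer while the maximum exceeds
the threshold (default 5). Worst-first iterative removal, rather than a
single pass, avoids over-dropping: removing one member of a collinear
cluster often rescues the rest. Exactly collinear layers get infinite VIF
and leave first. `pairwise_predictor_correlation()` reports Pearson
correlations on the same subsample so both screens see identical data.

The sampling-bias layer is a weighted Gaussian kernel density of the
occurrence records (bandwidth 3 km by default, each record weighted by its
individual count), min-max rescaled to $[0,1]$ with zero-density cells
exactly 0. It feeds `sample_background()`, which draws background cells
with probability proportional to the bias value, so the background sample
inherits the survey-effort pattern of the presences — the standard
target-group correction for presence-only sampling bias. Whether a given
species' model uses the bias layer is the caller's choice (pass `bias =`
or not); nothing downstream assumes it.

## The maximum-entropy model

The core of the package is an L1-penalized maximum-entropy density model
over landscape cells, fitted from scratch. Predictors are standardized to
$[0,1]$ by their background range and expanded into feature classes:
linear (L), quadratic (Q), all pairwise products (P), and forward/reverse
hinge features at 20 evenly spaced knots (H). The threshold class of the
original software is omitted: hinge features span the same step-like
responses, and dropping thresholds shrinks the grid without losing
expressiveness. The fitted weights $\lambda$ maximize

$$
\frac{1}{m}\sum_{i=1}^{m} \lambda^\top f(x_i)
\;-\; \log \frac{1}{n}\sum_{b=1}^{n} e^{\lambda^\top f(x_b)}
\;-\; \mathrm{rm} \sum_j \beta_j |\lambda_j|,
$$

the presence log-likelihood against the background partition function,
with per-feature penalties $\beta_j = 1/\sqrt{m}$ (linear, quadratic,
product) or $2.5/\sqrt{m}$ (hinge), scaled by the regularization
multiplier rm. These mirror the defaults of mainstream maxent
implementations in shape, not in their exact empirically tuned constants.
Optimization is proximal gradient ascent with backtracking line search and
soft-thresholding; convergence is declared when the largest weight change
falls below `tol` (default 1e-5) within `max_iter` iterations (default
500 — the protocol this follows states both 500 and 1,000 in different
places, so the cap is a visible argument). Hitting the cap flags the model
and warns rather than failing; with an L1 penalty the objective is concave
and the returned point is still usable.

Three output scales share the same ranking: `raw` is the normalized
exponential score (background mean exactly 1 — asserted after every fit);
`logistic` is $\tau r/((1-\tau) + \tau r)$ at prevalence $\tau = 0.5$; and
`cloglog` (the default map scale) is $1 - \exp(-e^{H} p)$ with $H$ the
entropy of the fitted background distribution and $p$ the raw score
normalized to sum 1 over the background — the entropy-based scaling of
standard maxent. A uniform model therefore maps to 0.5 (logistic) or
$1 - e^{-1} \approx 0.63$ (cloglog), not to 0.

Model selection follows the ENMeval-style design: every combination of
rm in 0.5--4 (step 0.5) and feature classes {L, LQ, H, LQH, LQHP} is
fitted under k-fold cross-validation (default 5), ranked by AICc with the
likelihood taken over landscape cells and K = nonzero weights; ties within
2 AICc units resolve by lower mean test omission, then higher mean test
AUC, then listing order. AUC is the Mann--Whitney statistic (ties count
one half). The MTSS threshold scans every unique predicted value — the
optimum always sits at one — and takes the smallest maximizer; P10 is the
type-7 10th percentile of presence scores. Binarization uses the >=
convention at the threshold (the source protocol mixes ">=" and ">"
wording; >= is applied uniformly and the cutoff itself is an argument,
with 0.9 the default for the "maximum suitability" class).

Variable importance comes in three views. Permutation importance permutes
one predictor over the evaluation cells and records the training-AUC drop,
normalized to sum 100. Percent contribution is a *path-independent
surrogate* for the original software's training-path accounting:
$\sum_j |\lambda_j| \cdot \mathrm{sd}(f_j)$ over the variable's features,
normalized to 100 — deliberately not identical to the original definition,
which depends on the optimization trajectory. Jackknife refits with only
and without each variable and reports the unpenalized training gain.

## Camera-trap density: the random encounter model

The REM converts a trapping rate $y/t$ (detections per camera-day, pooled
over stations) into density via the ideal-gas encounter rate:

$$ D = \frac{y}{t} \cdot \frac{\pi}{v\, r\, (2 + \theta)} $$

with speed $v$ (km/day), detection radius $r$ (km) and detection angle
$\theta$ (radians). This is the Rowcliffe gas-model form used by the
reference REM software. Applied papers occasionally print a different
arrangement, $D = (y/t)/(v \pi r^2 \theta)$; that variant is exposed as
`formula = "as_printed"` purely for auditability, and every estimate
records which formula produced it. The two are not interchangeable — the
printed variant is dimensionally different — and the gas-model form is the
default because it is the one the cited methodology actually computes.

Uncertainty is propagated by parametric bootstrap: $v \sim N(16, 6)$
km/day and $r \sim N(0.020, 0.002)$ km by default (a 20 m detection radius
with a 2 m standard deviation), 10,000 draws, non-positive draws excluded
(about 0.4% under the defaults — $\Phi(-16/6) \approx 0.0038$), the
density recomputed per draw, and the 2.5th/97.5th percentiles (type-7
interpolation) reported as the 95% interval. Because $1/v$ is convex, the
bootstrap mean sits above the plug-in estimate at the prior means under a
wide speed prior; both are reported, since "mean density" is ambiguous
between them. Population size over a suitability-selected area is
$\lceil \text{area} \times D \rceil$ — the "up to N individuals" reading —
with the unrounded product alongside.

## Spatial association

Three complementary statistics compare predator and prey distributions:

* **Mantel test** on pairwise Euclidean distance matrices of the two
  species' occurrence points: the statistic is the Pearson correlation of
  lower-triangle entries, the null is built by jointly permuting rows and
  columns of the second matrix, and the p-value is one-tailed upper with
  the $(\text{exceedances}+1)/(n_{\mathrm{perm}}+1)$ convention, so it can
  never be zero and never falls below 1/1000 at 999 permutations. Upper
  null quantiles (90/95/97.5/99%) are reported. For $n \le 7$ an exact
  mode enumerates all $n!$ relabelings. When the two species have unequal
  sample sizes the larger set is subsampled (seeded) to match — the
  underlying field protocol leaves this unspecified — and because that
  subsample is itself random, `mantel_association()` repeats it (default
  100 draws) and reports the median r and p with spread; a single-draw
  mode mimics a one-shot analysis.
* **Schoener's D** between suitability maps normalized to spatial
  probability distributions: $D = 1 - \frac{1}{2}\sum_i |p_i - q_i|$,
  symmetric, scale-invariant, 0 for disjoint support and 1 for identity.
* **Correlation suite** over cell values of aligned suitability rasters:
  Pearson on all complete rows; Spearman on rows that survive the
  all-zero-row filter (removing the shared unsuitable background that
  would otherwise inflate rank agreement) and a stratified seeded
  subsample capped at 5,000 rows. Strata are a 4x4 grid of equal-area
  spatial blocks with proportional allocation — "stratified random
  sampling" without a stated design is implemented as the simplest
  spatially balanced one. Each family of pairwise p-values is
  Benjamini--Hochberg adjusted. The zero-row filter is applied to the
  Spearman branch only, as described in the protocol this follows; a flag
  extends it to Pearson for sensitivity analysis.

## The synthetic-data module

Every stage is exercised against generated data with known ground truth:

* **Landscapes**: Gaussian-smoothed white noise (bandwidth 5 cells), the
  simplest stationary random field with tunable autocorrelation,
  standardized to unit variance; plus distance-transform layers derived by
  thresholding the first field into habitat patches, so the stack mixes
  smooth and distance-type predictors like a real Corine-derived stack.
* **Occurrences**: an inhomogeneous point process with intensity
  $\propto \exp(\beta^\top z)$ of the standardized layers, sampled by
  rejection; coefficients are per-SD effects. Dates are uniform over
  March 2023--April 2024 (the emulated collection window) to exercise
  deduplication; sources are assigned at random.
* **Camera encounters**: Poisson counts with the gas-model mean
  $t D v r (2+\theta)/\pi$ per camera — the exact forward model of the REM
  estimator, which is what makes density recovery a meaningful test.

All generators are pure functions of their seed. What the synthetic data
does *not* emulate: animal movement trajectories and home ranges (cameras
see independent Poisson streams, not a moving animal), roadkill's spatial
bias along roads, inter-species attraction or avoidance beyond shared
habitat preferences, and temporal structure within the collection window.
Passing recovery tests therefore demonstrates the estimators are
self-consistent under their own assumptions — not that those assumptions
hold in any particular field system. In particular the realized trapping
rate behind a published density is rarely printed, so synthetic camera
scenarios are parameterized from the stated priors, not calibrated to
field data.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
problems chosen as the smallest sizes at which each statistical claim is
testable: landscapes of 40x50 to 60x80 cells at 100 m, presence samples of
55--500, background samples of 200--2,000, 10,000 bootstrap draws, and
100--200 replicates for coverage and sign-recovery rates. Percentiles use
R's default type-7 interpolation throughout. Background features define
the $[0,1]$ feature scaling, and prediction clamps outside values to the
training range. Degenerate inputs fail loudly (all-zero bias or weights,
constant distance matrices, empty rasters) or are handled with a
documented convention (constant predictors get zero weight; a
single-variable model has permutation importance 100 by definition; AICc
with $n \le K+1$ is $+\infty$ so such a model cannot win selection).

## Known limitations

* Percent contribution is not the original path-dependent definition (see
  above); comparisons against software that tracks the training path will
  differ, sometimes substantially, while ranking usually agrees.
* The Mantel test between unpaired point sets of different sizes depends
  on the subsampling design; the repeated-draw median is a robustness
  device, not a canonical statistic.
* Proximal gradient is robust but not the fastest fitter; very tight
  tolerances (1e-8) on near-degenerate problems may hit the iteration cap
  and warn.
* No reprojection: inputs must share a projected CRS in meters.
* The KDE bias layer is evaluated densely (cells x points); for very
  large grids with tens of thousands of points an FFT-based density would
  be preferable.
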