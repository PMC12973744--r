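# predscape

Spatial predator–prey analysis for protected-area wildlife monitoring:
from multi-source occurrence records and environmental rasters to habitat
suitability maps, camera-trap density estimates with bootstrap
uncertainty, suitability-weighted population size, and predator–prey
spatial-association statistics.

The package is aimed at ecologists analysing a large carnivore and its
wild prey in a landscape surveyed with transects, camera traps, roadkill
reports and citizen science — the typical data mix of a Mediterranean
national park — and at methodologists who want every step of that
pipeline testable against synthetic data with known ground truth.

## What it computes

**Habitat suitability.** An L1-penalized maximum-entropy model fitted
from scratch over landscape cells. With presence features f(x), weights
λ maximize

    mean_presence(λ·f) − log mean_background(exp(λ·f)) − rm·Σ β_j |λ_j|

with feature classes L/Q/P/H (linear, quadratic, product, hinge),
per-feature penalties β scaled by the regularization multiplier rm, and
raw/logistic/cloglog output scales. Tuning fits an RM × feature-class
grid under k-fold cross-validation and ranks by AICc with omission and
AUC tie-breaking. Thresholds: maximum training sensitivity plus
specificity (MTSS) and the 10th-percentile training presence (P10).
Diagnostics: percent contribution, permutation importance, jackknife
gains, response curves.

**Density.** The Random Encounter Model converts the pooled camera
trapping rate y/t into density

    D = (y/t) · π / (v · r · (2 + θ))

(speed v km/day, detection radius r km, detection angle θ radians), with
parametric-bootstrap confidence intervals (v ~ N(16, 6) km/day,
r ~ N(20 m, 2 m) by default, 10,000 draws, percentile CI) and population
extrapolation N = ⌈area × D⌉ over the cells at or above a suitability
cutoff.

**Spatial association.** Seeded Mantel permutation tests on occurrence
distance matrices (with an exact-enumeration mode for small n),
Schoener's D niche overlap between suitability maps, and a
Pearson/Spearman correlation suite over raster cells with all-zero-row
filtering, stratified subsampling capped at 5,000 cells, and
Benjamini–Hochberg correction.

**Synthetic data.** Gaussian-random-field landscapes with
distance-to-habitat layers, occurrence points from an inhomogeneous point
process with known coefficients, and Poisson camera encounters generated
by the exact forward model of the REM — so suitability, density and
association estimates can all be checked against their generating truth.

Everything tabular flows as tibbles; fitted objects have `tidy()` /
`glance()` methods and `autoplot()` / `plot_response_curves()` graphics.
Rasters travel as a lightweight `raster_grid` class with plain-text ESRI
ASCII grid I/O.

## Worked example

```r
library(predscape)

extent <- c(0, 0, 6000, 5000)
stack <- generate_predictor_stack(seed = 42, extent = extent,
                                  cell_size = 100, n_layers = 3)
truth <- scenario_truth(
  seed = 1, true_density = 1.2, true_speed = 16, true_radius = 0.020,
  true_angle = 0.77,
  species_coefficients = list(wolf = c(1.5, 0.5, -0.3),
                              roe_deer = c(1.2, 0.8, -0.2)),
  extent = extent, cell_size = 100)

occ <- generate_occurrences(truth, stack, c(wolf = 280, roe_deer = 126)) |>
  deduplicate_occurrences() |>
  thin_to_grid(stack[[1]])
summary(occ)
#> # A tibble: 2 × 5
#>   species      n first_date last_date  n_sources
#>   <chr>    <int> <date>     <date>         <int>
#> 1 roe_deer   117 2023-03-03 2024-04-30         4
#> 2 wolf       228 2023-03-01 2024-04-30         4
```

280 wolf and 126 roe-deer records were generated; deduplication and
one-per-cell thinning reduce them to 228 and 117. Fit and evaluate a
suitability model with bias-corrected background:

```r
bias <- kde_bias_layer(occ, stack[[1]], sigma = 3000)
bg <- sample_background(stack, n = 1000, bias = bias, seed = 2)
ev <- cv_evaluate(occ[occ$species == "wolf", ], stack, bg,
                  fc = "LQ", rm = 1, k = 5, seed = 3)
ev
#> <eval_report> FC=LQ RM=1, 5-fold CV
#>   train AUC 0.786 +/- 0.0059; test AUC 0.786 +/- 0.0241
#>   mean omission 0.154; AICc 3367.19 (K=2)

suit <- predict_suitability(ev$model, stack, output = "cloglog")
```

Test AUC ≈ 0.79 says presences rank above background cells 79% of the
time under cross-validation. Density from a simulated camera campaign
(48 stations × 100 days), then population size over the
highest-suitability cells:

```r
cams <- simulate_camera_encounters(truth, n_cameras = 48, effort_days = 100)
est <- rem_bootstrap(cams, n_sims = 10000, seed = 4)
est
#> <rem_estimate> D = 1.620 ind/km^2 (95% CI 0.690-4.363), formula=rowcliffe
#>   trapping rate 0.3454/day; plug-in D 1.224; 10000 sims, 41 excluded

population_size(suitable_area(suit, 0.9), est$density)
#> # A tibble: 1 × 4
#>   area_km2 density expected population
#>      <dbl>   <dbl>    <dbl>      <dbl>
#> 1     0.91    1.62     1.47          2
```

The plug-in estimate (1.22 ind/km²) recovers the simulated truth of 1.2;
the bootstrap mean (1.62) sits higher because density is convex in the
speed draw — both are reported, and the 95% interval covers the truth.
On this small toy landscape only 0.91 km² clears the 0.9 suitability
cutoff, supporting up to 2 individuals.

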