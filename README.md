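# eskrig

Geostatistical mapping and driver analysis of plot-level ecosystem services.

Field inventories of urban-forest ecosystem services — carbon storage and
sequestration (kg), avoided surface runoff (m³/yr), air-pollution removal
(g/yr) — measure a few hundred plots laid out by grid-random sampling, but
planners need maps and driver attributions for whole regions. `eskrig`
implements the standard geostatistical chain that bridges the two, for
ecologists and urban planners working with plot tables in projected planar
coordinates:

- **Composite score** — Min–Max normalization
  `X' = (X − X_min)/(X_max − X_min)` per service, equal-weight sum,
  renormalized onto [0, 1] (`composite_es()`), with moment-based skewness
  and Pearson kurtosis diagnostics (`distribution_diagnostics()`).
- **Semivariogram** — Matheron estimator
  `γ(h) = (1/2N(h)) Σ (x_i − x_j)²` binned on lag-step multiples
  (`empirical_semivariogram()`), lag step from the average nearest-neighbor
  distance, weighted-least-squares spherical fit (`fit_spherical_model()`),
  and nugget-to-sill classification of spatial dependence — Co/C < 25 %
  strong, 25–75 % moderate, > 75 % weak
  (`classify_spatial_dependence()`).
- **Ordinary kriging** — `Ẑ(x₀) = Σ λᵢ Z(xᵢ)` with `Σ λᵢ = 1`, at points or
  on a grid written as ESRI ASCII raster (`ordinary_kriging_predict()`,
  `krige_grid()`), plus 90/10 hold-out and leave-one-out cross-validation
  reporting `ME = mean(xᵢ − x̂ᵢ)` and `RMSE = √(mean((xᵢ − x̂ᵢ)²))`
  (`cross_validate()`).
- **Hot/cold spots** — Getis–Ord `Gᵢ*(d) = Σⱼ Wᵢⱼ(d) Xⱼ / Σⱼ Xⱼ` over binary
  distance-band weights, z-scored with the standard randomization moments
  and classified at |z| ≥ 1.65/1.96/2.58 (`getis_ord_gi_star()`).
- **Geographical detector** — factor detector
  `q = 1 − Σₘ Nₘ σₘ² / (N σ²)` with noncentral-F significance, Jenks
  natural-breaks discretization of continuous drivers, and the five-way
  interaction classification against min, max and `q(A)+q(B)`
  (`jenks_breaks()`, `factor_q()`, `interaction_q()`, `run_geodetector()`).
- **Synthetic surveys** — grid-random sampling, lognormal service fields
  with exact spherical spatial covariance, and zonal drivers with tunable
  explanatory power (`grid_random_sample()`, `simulate_es_field()`,
  `simulate_driver_layers()`), so every stage is validated against known
  ground truth.

## Worked example

The default configuration simulates a 30 km × 35 km survey (120 plots on a
2500 m grid after 20 % cell exclusion, three lognormal services, one
informative and one pure-noise driver) and runs the full chain:

```r
library(eskrig)
res <- run_pipeline(default_pipeline_config(seed = 42), output_dir = "out")
print(res$variogram$model)
print(res$cv)
print(res$geodetector$factors)
```

```
pipeline: starting (seed 42)
pipeline: 120 plots, services: carbon_storage, avoided_runoff, pollution_removal
pipeline: variogram Co/C = 24.3% (strong), a = 6540 m
pipeline: cross-validation ME = -0.6350, RMSE = 1.0878
spherical variogram model: Co = 0.261, C = 1.072, a = 6540.4 m
  Co/C = 24.34% (strong spatial dependence)
kriging cross-validation (holdout, seed 242): n_train = 108, n_test = 12
  ME = -0.63498, RMSE = 1.08776
           driver          q         p significant
1  population_cov 0.58782001 0.7573142       FALSE
2 population_zone 0.01347145 1.0000000       FALSE
3        gdp_zone 0.01347145 1.0000000       FALSE
4         gdp_cov 0.00428692 1.0000000       FALSE
```

Reading the output: the fitted spherical model recovers the simulated
log-scale field (true sill 1.0, range 8000 m); its nugget-to-sill ratio of
24.3 % classifies the field as strongly spatially dependent, i.e. worth
kriging. Cross-validation holds out 12 of 120 plots (90/10) and reports the
log-scale bias (ME) and accuracy (RMSE) of kriging them from the rest. In
the driver table, the covariate built to track the field (`population_cov`)
earns a factor-detector q of 0.59 — it explains 59 % of the field's
variance after 5-class natural-breaks discretization — while the pure-noise
driver (`gdp_cov`) sits near 0; the conservative noncentral-F p-values are
best read comparatively. `out/` receives the plot table, diagnostics,
variogram tables, the kriged surface (`surface.asc`), cross-validation
residuals, the hotspot table, the geodetector tables, and a JSON manifest
with an MD5 hash of every artifact.

A thin command-line front end with `run`/`simulate`/`variogram`/`krige`/
`hotspot`/`geodetect` verbs is installed at `inst/scripts/espipe.R`
(`Rscript espipe.R run --config inst/extdata/example_config.yml`).

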