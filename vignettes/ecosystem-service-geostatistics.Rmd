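---
title: "Geostatistical mapping and driver analysis of plot-level ecosystem services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical mapping and driver analysis of plot-level ecosystem services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eskrig)
```

## The problem

Urban-forest ecosystem services — carbon storage and sequestration, avoided
surface runoff, air-pollution removal — are estimated at field plots, but
management questions are asked about whole districts. Turning a few hundred
plot values into a defensible map, and asking which socio-economic layers
explain its spatial pattern, is a geostatistical problem with a
well-established recipe:

1. check distributional assumptions, log-transforming skewed services;
2. normalize services of incommensurable units onto $[0,1]$ and combine them
   into an equal-weight composite score;
3. estimate the empirical semivariogram, fit a spherical model, and classify
   the strength of spatial dependence from the nugget-to-sill ratio;
4. interpolate by ordinary kriging and quantify accuracy by hold-out or
   leave-one-out cross-validation (mean error and RMSE);
5. locate statistically significant clusters of high and low values with the
   Getis–Ord $G_i^*$ statistic;
6. attribute spatial heterogeneity to drivers with the geographical-detector
   $q$-statistic and its interaction detector.

`eskrig` implements this chain as composable functions plus a single
`run_pipeline()` entry point, and pairs it with a synthetic-survey generator
so that every stage is validated against data with known ground truth.

## Models and statistics

### Composite ecosystem-service score

Each service column $X$ is Min–Max normalized,
$X' = (X - X_{\min}) / (X_{\max} - X_{\min})$, an order-preserving linear map
onto $[0,1]$. Normalized services are summed with equal weights (no service
dominates by unit or magnitude) and the sum is normalized again, so the
composite also spans $[0,1]$ and attains both endpoints. Constant columns are
rejected rather than silently mapped to zero: a degenerate range means the
normalization is undefined. Weights are configurable but default to equal;
the composite is invariant to positive affine rescaling of any input and to
the order of services.

Distribution diagnostics report moment-based skewness $g_1 = m_3/m_2^{3/2}$
and Pearson kurtosis $m_4/m_2^2$ (normal $\approx 3$, not 0 — the convention
under which reference values near 3 indicate near-normality). Kriging is run
on log-transformed services by default, because lognormal-like service
magnitudes become approximately normal only after the log; the composite, by
contrast, is built from raw magnitudes, since normalization itself removes
units. Both choices are explicit in the configuration.

### Semivariogram and spatial dependence

The empirical semivariogram uses the Matheron estimator,
$\gamma(h) = \frac{1}{2N(h)} \sum_{N(h)} (x_i - x_j)^2$, over unordered
pairs binned into left-closed intervals $[kh, (k{+}1)h)$. The lag step
defaults to the average nearest-neighbor distance (so each bin holds at
least a few pairs) and the number of lags to
$\mathrm{round}(d_{\max}/2/h)$ — the lag span covers about half the maximum
pairwise separation, beyond which bins are thin and unreliable. Both are
overridable.

The spherical model
$\gamma(h) = C_0 + (C - C_0)\,(1.5\,h/a - 0.5\,(h/a)^3)$ for $h \le a$, $C$
beyond, is fitted by weighted least squares with Cressie-style weights
$N(h)/\gamma_{\text{model}}(h)^2$ by default. We measured both weightings on
simulated surveys at the package's study scale (240 plots, 30 × 35 km,
$C_0/C = 20\%$): plain pair-count weights let the many long-range pairs
dominate and leave the nugget so poorly determined that the fitted
nugget-to-sill ratio ranged from 0% to 55%; Cressie weights, which emphasize
the short, low-semivariance lags where the nugget lives, recover it tightly.
Pair-count weighting remains available via `weights = "npairs"`. The fit is
a deterministic bounded multi-start L-BFGS-B over a fixed grid of starting
values, polished with `nlminb` to machine precision; the range is bounded
below by the smallest sampled lag because shorter ranges are
unidentifiable (any nugget/partial-sill split fits equally well).

Spatial dependence is classified by the nugget-to-sill percentage $C_0/C$:
below 25% strong, 25–75% moderate, above 75% weak.

### Ordinary kriging and cross-validation

Predictions $\hat Z(x_0) = \sum_i \lambda_i Z(x_i)$ solve the ordinary-kriging
system built from the fitted variogram, augmented with the unbiasedness
constraint $\sum_i \lambda_i = 1$ and a Lagrange multiplier; the kriging
variance is $\sum_i \lambda_i \gamma(x_i, x_0) + \mu$. The diagonal uses
$\gamma(0) = 0$ (the nugget is a discontinuity at the origin), so prediction
at a data point is exact, with zero variance when $C_0 = 0$. The default
neighborhood is global (all training points; the augmented matrix is
factorized once for all targets), with a nearest-$k$ option for larger
problems.

Cross-validation supports a seeded hold-out split with
$n_{\text{train}} = \mathrm{round}(n(1-f))$ — at $n = 240$, $f = 0.10$ this
is exactly 216/24 — and leave-one-out. Mean error
$\mathrm{ME} = \frac{1}{n}\sum (x_i - \hat x_i)$ measures systematic bias
and $\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum (x_i - \hat x_i)^2}$ overall
accuracy; residuals are observed minus predicted throughout, and candidate
models are ranked by smaller RMSE with ties broken toward ME nearest zero.
Predictions stay on the transformed (log) scale by default, since that is
the scale the variogram was fitted on; an optional lognormal back-transform
$\exp(\hat z + \sigma^2_k/2)$ is available behind a flag.

### Hot and cold spots

$G_i^*(d) = \sum_j W_{ij}(d) X_j / \sum_j X_j$ compares each point's
distance-band neighborhood sum (self included — the star convention) to the
global sum. Its z-score uses the standard Getis–Ord randomization moments,
and categories follow the two-sided thresholds $|z| \ge 2.58$ (99%), $1.96$
(95%), $1.65$ (90%), signed hot/cold. The statistic assumes nonnegative
values, so inputs with a negative minimum (log scale) are shifted positive
first; the shift is recorded and provably leaves z-scores unchanged. The
default band is twice the variogram lag step — wide enough that every plot
has several neighbors under grid-random sampling — and a
`distance_threshold_sweep()` traces how significant patches merge as the
band grows. No multiplicity correction is applied across points; the raw
thresholds are the field's convention for these maps.

### Geographical detector

Continuous drivers are discretized into $k = 5$ classes by Jenks natural
breaks (Fisher's exact dynamic programme; deterministic, ties to the lower
break). The factor detector is
$q = 1 - \sum_m N_m \sigma_m^2 / (N \sigma^2)$ with population variances, so
the within/total decomposition is exact and $q \in [0,1]$; refining a
stratification never decreases $q$. Significance uses the noncentral-F test
of the geographical detector with $F = \frac{N-L}{L-1}\frac{q}{1-q}$ and a
noncentrality computed from stratum means; factors with $p < 0.1$ are
flagged. The interaction detector computes $q$ of the cross-classification
$A \times B$ and classifies it against $\min$, $\max$ and the sum
$q(A) + q(B)$ (equality with the sum, within $10^{-9}$, is independence);
the cross-classification refines both factors, so enhancement beyond the
maximum is the typical outcome for genuinely joint influences.

## The synthetic survey generator

The generator emulates a grid-random plot inventory over a rectangular
region of about 1000 km² (30 × 35 km):

- **Sampling.** The region is tiled by square cells (2500 m by default); a
  seeded random subset of cells is excluded — a stand-in for plots dropped
  in the field as inaccessible or redundant, for which no spatial rule is
  available — and one point is placed uniformly within each selected cell.
  Per-cell selection frequency is uniform across non-excluded cells.
- **Service fields.** Log-scale values are drawn from a Gaussian random
  field whose covariance is the spherical model's
  ($C(h) = (C - C_0)(1 - 1.5h/a + 0.5(h/a)^3)$ within the range), plus
  independent nugget noise per plot — the measurement-error reading of
  $C_0$ — then exponentiated, giving positive, lognormal services that are
  normal after log transform. A Cholesky factorization with escalating
  jitter guards positive definiteness.
- **Drivers.** The sampled extent is split into contiguous vertical bands
  (simple, reproducible zone geometry with trivial point-in-zone tests);
  each zone draws a coupling strength $|N(0, \sigma_{\text{zone}})|$ and the
  continuous covariate is that strength times the plot's standardized log
  field plus noise. Coupling strengths are kept nonnegative deliberately:
  with signed couplings, zones of opposite sign fold high and low field
  values into the same covariate class after discretization, capping the
  attainable $q$ near 0.2 regardless of signal strength, whereas nonnegative
  couplings make the covariate monotone in the field within every zone and
  the detector's $q$ cleanly tunable from 0 (no effect) towards 1.

Default study conditions: 120 plots on the 2500 m grid with 20% cell
exclusion for the demonstration pipeline (240 one-per-cell plots cannot fit
a 2500 m tiling of this region, whose ~168 cells reflect the coarse grid of
the emulated survey design); the validation experiments in the test-suite
use 240 plots on a finer 1500 m grid with 10% exclusion, field parameters
$C_0 = 0.2$, $C = 1.0$, $a = 8000$ m, and 20 replicate seeds. Simulated
plots are independent draws with exact spherical covariance; they do not
emulate land-cover structure, anisotropy, measurement censoring, or the
spatial clustering of real exclusions, so passing tests demonstrate
statistical correctness of the estimators under the assumed model, not
robustness to real-survey artifacts.

## Numerical choices

- Variogram bins are left-closed, right-open on lag-step multiples;
  unordered pairs are counted once; empty bins carry `NA` and are excluded
  from fitting (at least four populated lags are required).
- The kriging solver reports weights and the Lagrange multiplier; kriging
  variances in $(-10^{-8}, 0)$ from round-off are clipped to zero and
  flagged; duplicate training locations raise a conditioning error naming
  the pair rather than producing a silently singular solve.
- $G_i^*$ denominators with negative randomization variance (possible only
  degenerately) are clipped with a flag; z-scores are `NA` there.
- Jenks uses exact $O(kn^2)$ dynamic programming — at survey scale
  ($n \le$ a few thousand) this is fast and exactly optimal, verified
  against exhaustive partition enumeration.
- All simulation, sampling and splitting functions take explicit integer
  seeds and restore the caller's RNG state, so runs are reproducible and
  composable; the pipeline derives per-stage seeds from one global seed.

## Known limitations

Only the spherical variogram form is implemented (the form used for this
class of plot surveys); anisotropy, co-kriging, universal kriging and trend
surfaces are out of scope. Geodetector risk and ecological detectors are not
provided. Coordinates are planar metres with no CRS handling. The
noncentral-F significance test for $q$ is conservative when strata are
estimated from the data (as with Jenks discretization of a continuous
driver), so its p-values are best read comparatively.
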