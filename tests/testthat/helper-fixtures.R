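# shared fixtures: seeded point patterns and simulated fields

rand_locations <- function(n, seed, width = 30000, height = 35000) {
  set.seed(seed)
  data.frame(x = runif(n, 0, width), y = runif(n, 0, height))
}

# grid-random plot sample dense enough to hold `n` plots in a 30 x 35 km region
study_plots <- function(n = 240, seed = 1, cell = 1500) {
  region <- region_spec(0, 0, 30000, 35000)
  design <- sampling_design(cell, n_target = n, exclusion_fraction = 0.1,
                            seed = seed)
  grid_random_sample(region, design)
}

sim_log_field <- function(locations, nugget, sill, range_m, mean_log = 0,
                          seed = 1) {
  spec <- synthetic_field_spec(variogram_model(nugget, sill, range_m),
                               mean_log = mean_log, seed = seed)
  log(simulate_es_field(locations, spec))
}

# exhaustive pair-enumeration semivariogram: the Matheron estimator computed
# pair by pair, independently of the package's vectorized binning
brute_semivariogram <- function(locations, values, lag_step, n_lags,
                                max_dist = n_lags * lag_step) {
  n <- nrow(locations)
  sums <- numeric(n_lags)
  counts <- integer(n_lags)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((locations$x[i] - locations$x[j])^2 +
                  (locations$y[i] - locations$y[j])^2)
      if (d > max_dist || d >= n_lags * lag_step) next
      k <- floor(d / lag_step) + 1
      sums[k] <- sums[k] + (values[i] - values[j])^2
      counts[k] <- counts[k] + 1L
    }
  }
  ifelse(counts > 0, sums / (2 * counts), NA_real_)
}

# direct two-pass variance-decomposition q, independent of factor_q
brute_q <- function(y, g) {
  g <- as.character(g)
  N <- length(y)
  popvar <- function(u) sum((u - mean(u))^2) / length(u)
  within <- 0
  for (lev in unique(g)) {
    ys <- y[g == lev]
    within <- within + length(ys) * popvar(ys)
  }
  1 - within / (N * popvar(y))
}

# per-point Gi* z-score from the standard randomization moments, written as
# an explicit scalar loop independent of the package's matrix implementation
brute_gi_star_z <- function(values, locations, d) {
  n <- length(values)
  xbar <- mean(values)
  s <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wij <- numeric(n)
    for (j in seq_len(n)) {
      dij <- sqrt((locations$x[i] - locations$x[j])^2 +
                    (locations$y[i] - locations$y[j])^2)
      wij[j] <- as.numeric(dij <= d)
    }
    Wi <- sum(wij)
    S1i <- sum(wij^2)
    num <- sum(wij * values) - xbar * Wi
    den <- s * sqrt((n * S1i - Wi^2) / (n - 1))
    z[i] <- num / den
  }
  z
}
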