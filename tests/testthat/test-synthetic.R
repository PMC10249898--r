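test_that("grid tiling uses ceiling arithmetic", {
  region <- region_spec(0, 0, 10000, 10000)
  expect_equal(unname(grid_cell_counts(region, 2500)["n_cells"]), 16L)
  # non-divisible extents round the cell count up
  expect_equal(unname(grid_cell_counts(region, 3000)["n_cells"]), 16L)
})

test_that("grid-random sampling places at most one in-bounds point per cell", {
  region <- region_spec(0, 0, 30000, 35000)
  design <- sampling_design(2500, n_target = 120, exclusion_fraction = 0.2,
                            seed = 42)
  pts <- grid_random_sample(region, design)
  expect_equal(nrow(pts), 120)

  # brute-force cell membership from coordinates
  nx <- ceiling(30000 / 2500)
  cell_of <- floor(pts$x / 2500) + nx * floor(pts$y / 2500) + 1
  expect_equal(sort(cell_of), sort(pts$cell))
  expect_false(any(duplicated(cell_of)))

  # each point inside its own cell's bounds
  ix <- (pts$cell - 1) %% nx
  iy <- (pts$cell - 1) %/% nx
  expect_true(all(pts$x >= ix * 2500 & pts$x <= (ix + 1) * 2500))
  expect_true(all(pts$y >= iy * 2500 & pts$y <= (iy + 1) * 2500))
})

test_that("sampling is deterministic and errors when the design exceeds cells", {
  region <- region_spec(0, 0, 10000, 10000)
  design <- sampling_design(2500, n_target = 10, seed = 3)
  expect_identical(grid_random_sample(region, design),
                   grid_random_sample(region, design))
  bad <- sampling_design(2500, n_target = 17, seed = 3)
  expect_error(grid_random_sample(region, bad), "17.*16|exceeds")
  # exclusion shrinks the available pool
  bad2 <- sampling_design(2500, n_target = 14, exclusion_fraction = 0.25,
                          seed = 3)
  expect_error(grid_random_sample(region, bad2), "exceeds")
})

test_that("per-cell selection frequency is uniform over seeds", {
  region <- region_spec(0, 0, 10000, 10000)
  counts <- integer(16)
  for (s in 1:400) {
    design <- sampling_design(2500, n_target = 8, seed = s)
    pts <- grid_random_sample(region, design)
    counts[pts$cell] <- counts[pts$cell] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("degenerate zero-variance field collapses to exp(mean_log)", {
  pts <- rand_locations(25, seed = 1)
  spec <- synthetic_field_spec(variogram_model(0, 0, 5000),
                               mean_log = 2, seed = 9)
  vals <- simulate_es_field(pts, spec)
  expect_equal(vals, rep(exp(2), 25))
})

test_that("field simulation is seeded, positive, and recovers its moments", {
  pts <- study_plots(n = 240, seed = 5)
  spec <- synthetic_field_spec(variogram_model(0.2, 1.0, 8000),
                               mean_log = 3, seed = 11)
  v1 <- simulate_es_field(pts, spec)
  v2 <- simulate_es_field(pts, spec)
  expect_identical(v1, v2)
  expect_true(all(v1 > 0))

  # mean and variance of log values recover mean_log and the sill; pooling
  # independent replicate fields keeps the spatially correlated sampling
  # error of either moment small
  logs <- unlist(lapply(1:10, function(s) {
    sp <- synthetic_field_spec(variogram_model(0.2, 1.0, 8000),
                               mean_log = 3, seed = 1000 + s)
    log(simulate_es_field(pts, sp))
  }))
  expect_lt(abs(mean(logs) - 3), 0.2)
  expect_lt(abs(var(logs) - 1.0), 0.15)
})

test_that("simulated field reproduces its generating variogram at short and long lags", {
  pts <- rand_locations(2000, seed = 2, width = 40000, height = 40000)
  z <- sim_log_field(pts, nugget = 0.1, sill = 1.0, range_m = 8000, seed = 21)
  emp <- empirical_semivariogram(pts, z, lag_step = 1000, n_lags = 30)
  # lags well inside the range: gamma near the nugget end, far below the sill
  short <- emp$gamma[1]
  long <- mean(emp$gamma[emp$lag > 10000], na.rm = TRUE)
  expect_gt(short, 0.05)
  expect_lt(short, 0.35)
  expect_gt(long, 0.8)
  expect_lt(long, 1.25)
})

test_that("driver layers carry tunable signal with in-range zone labels", {
  pts <- study_plots(n = 240, seed = 7)
  z <- sim_log_field(pts, 0.2, 1.0, 8000, seed = 7)

  null_spec <- driver_spec(n_zones = 5, zone_effect_sd = 0, noise_sd = 1,
                           seed = 13)
  dl <- simulate_driver_layers(pts, z, null_spec)
  expect_true(all(dl$zone %in% 1:5))
  expect_identical(dl, simulate_driver_layers(pts, z, null_spec))
  # zero zone effect: zone id carries no information about the field
  expect_lt(factor_q(z, dl$zone)$q, 0.1)

  expect_error(
    simulate_driver_layers(pts[1:3, ], z[1:3],
                           driver_spec(5, 1, 0.1, seed = 1)),
    "fewer plots")
})

test_that("strong zonal drivers are recovered by the factor detector", {
  qs <- vapply(1:20, function(s) {
    pts <- study_plots(n = 240, seed = s)
    z <- sim_log_field(pts, 0.2, 1.0, 8000, seed = s)
    dl <- simulate_driver_layers(
      pts, z, driver_spec(n_zones = 5, zone_effect_sd = 2, noise_sd = 0.1,
                          seed = s + 500))
    factor_q(z, jenks_breaks(dl$covariate, 5))$q
  }, numeric(1))
  expect_gt(median(qs), 0.5)
})
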