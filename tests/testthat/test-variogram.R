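test_that("average nearest-neighbor distance matches brute force", {
  two <- data.frame(x = c(0, 100), y = c(0, 0))
  expect_equal(average_nearest_neighbor_distance(two), 100)

  corners <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  expect_equal(average_nearest_neighbor_distance(corners), 1)

  pts <- rand_locations(50, seed = 3)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  expect_equal(average_nearest_neighbor_distance(pts),
               mean(apply(d, 1, min)), tolerance = 1e-12)

  dup <- data.frame(x = c(0, 0, 5), y = c(0, 0, 0))
  expect_warning(average_nearest_neighbor_distance(dup), "share coordinates")
  expect_error(average_nearest_neighbor_distance(two[1, ]), "at least 2")
})

test_that("lag structure follows the half-max rule with override", {
  # ANN 1000 m, max distance 30000 m -> 15 lags
  pts <- data.frame(x = seq(0, 30000, by = 1000), y = 0)
  ls <- lag_structure(pts)
  expect_equal(ls$lag_step, 1000)
  expect_equal(ls$max_dist, 30000)
  expect_equal(ls$n_lags, 15L)
  expect_equal(lag_structure(pts, n_lags = 15)$n_lags, 15L)

  rnd <- rand_locations(60, seed = 9)
  expect_equal(lag_structure(rnd)$max_dist, max(dist(rnd)), tolerance = 1e-12)
  expect_error(lag_structure(data.frame(x = c(1, 1), y = c(2, 2))),
               "collocated")
})

test_that("empirical semivariogram reproduces hand-enumerated pairs", {
  # collinear points at x = 0, 1, 2 with values 0, 1, 3
  pts <- data.frame(x = c(0, 1, 2), y = 0)
  emp <- empirical_semivariogram(pts, c(0, 1, 3), lag_step = 1, n_lags = 3)
  # bin [1,2): pairs (0,1) and (1,2) -> (1 + 4) / (2*2); bin [2,3): pair (0,2)
  expect_equal(emp$gamma[2], 1.25)
  expect_equal(emp$gamma[3], 4.5)
  expect_equal(emp$n_pairs, c(0L, 2L, 1L))
  expect_true(is.na(emp$gamma[1]))

  # constant field: zero semivariance at every populated lag
  flat <- empirical_semivariogram(rand_locations(30, 2), rep(4, 30),
                                  lag_step = 5000, n_lags = 8)
  expect_true(all(flat$gamma[flat$n_pairs > 0] == 0))

  # linear drift: values equal to x give gamma = dist^2 / 2 within each bin
  line <- data.frame(x = seq(0, 2000, by = 100), y = 0)
  drift <- empirical_semivariogram(line, line$x, lag_step = 100, n_lags = 10)
  pop <- drift$n_pairs > 0
  expect_equal(drift$gamma[pop],
               vapply(which(pop), function(k) {
                 # per-bin mean of d^2/2 over realized pair separations
                 ds <- dist(line$x)
                 ds <- ds[ds >= (k - 1) * 100 & ds < k * 100]
                 mean(ds^2) / 2
               }, numeric(1)),
               tolerance = 1e-10)
})

test_that("binned semivariances equal exhaustive pair enumeration", {
  for (s in 1:5) {
    pts <- rand_locations(30, seed = s, width = 10000, height = 10000)
    set.seed(s + 50)
    v <- rnorm(30)
    emp <- empirical_semivariogram(pts, v, lag_step = 1500, n_lags = 6)
    expect_equal(emp$gamma, brute_semivariogram(pts, v, 1500, 6),
                 tolerance = 1e-12)
  }
})

test_that("binning is pure: a bin's gamma is unchanged by adding more bins", {
  pts <- rand_locations(40, seed = 12)
  set.seed(13)
  v <- rnorm(40)
  few <- empirical_semivariogram(pts, v, lag_step = 3000, n_lags = 5)
  many <- empirical_semivariogram(pts, v, lag_step = 3000, n_lags = 9)
  expect_equal(few$gamma, many$gamma[1:5])
  expect_equal(few$n_pairs, many$n_pairs[1:5])
})

test_that("spherical fit recovers noiseless parameters and the nugget limit", {
  truth <- variogram_model(0.1, 1.0, 5000)
  h <- seq(250, 9750, by = 500)
  emp <- data.frame(lag = h, dist_avg = h, gamma = spherical_gamma(h, truth),
                    n_pairs = rep(50L, length(h)))
  fit <- fit_spherical_model(emp)
  expect_equal(fit$nugget, 0.1, tolerance = 1e-6)
  expect_equal(fit$sill, 1.0, tolerance = 1e-6)
  expect_equal(fit$range, 5000, tolerance = 1e-2)

  # flat variogram: everything is nugget
  flat <- data.frame(lag = h, dist_avg = h, gamma = rep(0.8, length(h)),
                     n_pairs = rep(50L, length(h)))
  ffit <- fit_spherical_model(flat)
  expect_gte(ffit$nugget / ffit$sill, 0.99)

  expect_error(fit_spherical_model(emp[1:3, ]), "4 populated lags")
})

test_that("fitted sill stays near the sample variance on simulated fields", {
  pts <- study_plots(n = 240, seed = 31)
  z <- sim_log_field(pts, 0.2, 1.0, 8000, seed = 31)
  ls <- lag_structure(pts)
  emp <- empirical_semivariogram(pts, z, ls$lag_step, ls$n_lags, ls$max_dist)
  fit <- fit_spherical_model(emp)
  s2 <- var(z)
  expect_gt(fit$sill, 0.25 * s2)
  expect_lt(fit$sill, 4 * s2)
})

test_that("nugget-to-sill ratio classifies spatial dependence", {
  expect_equal(classify_spatial_dependence(
    variogram_model(0.2131, 1, 5000))$label, "strong")
  expect_equal(classify_spatial_dependence(
    variogram_model(0.3048, 1, 5000))$label, "moderate")
  expect_equal(classify_spatial_dependence(
    variogram_model(0.6033, 1, 5000))$label, "moderate")
  expect_equal(classify_spatial_dependence(
    variogram_model(0.80, 1, 5000))$label, "weak")
  # boundary conventions: 25 and 75 are moderate
  expect_equal(classify_spatial_dependence(
    variogram_model(0.25, 1, 1))$label, "moderate")
  expect_equal(classify_spatial_dependence(
    variogram_model(0.75, 1, 1))$label, "moderate")
  expect_error(classify_spatial_dependence(variogram_model(0, 0, 1)),
               "degenerate")
})
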