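test_that("kriging with zero nugget interpolates training points exactly", {
  pts <- rand_locations(25, seed = 14, width = 10000, height = 10000)
  set.seed(15)
  v <- rnorm(25)
  model <- variogram_model(0, 1.0, 4000)
  pred <- ordinary_kriging_predict(pts, v, model, pts)
  expect_equal(pred$prediction, v, tolerance = 1e-8)
  expect_equal(pred$variance, rep(0, 25), tolerance = 1e-8)
  w <- attr(pred, "weights")
  expect_equal(diag(w), rep(1, 25), tolerance = 1e-8)
})

test_that("kriging weights always sum to one", {
  pts <- rand_locations(40, seed = 16)
  set.seed(17)
  v <- rnorm(40)
  model <- variogram_model(0.3, 1.2, 9000)
  targets <- rand_locations(100, seed = 18)
  pred <- ordinary_kriging_predict(pts, v, model, targets)
  expect_equal(rowSums(attr(pred, "weights")), rep(1, 100), tolerance = 1e-10)
  # and with a restricted neighborhood
  predk <- ordinary_kriging_predict(pts, v, model, targets,
                                    neighborhood_size = 12)
  expect_equal(rowSums(attr(predk, "weights")), rep(1, 100), tolerance = 1e-10)
})

test_that("prediction matches an independent dense solve of the same system", {
  train <- data.frame(x = c(0, 1000, 400), y = c(0, 200, 900))
  v <- c(2.0, 3.5, 1.0)
  model <- variogram_model(0.1, 1.0, 1500)
  target <- data.frame(x = 450, y = 350)

  gam <- function(h) ifelse(h == 0, 0,
    ifelse(h < 1500, 0.1 + 0.9 * (1.5 * h / 1500 - 0.5 * (h / 1500)^3), 1.0))
  dmat <- as.matrix(dist(train))
  A <- rbind(cbind(gam(dmat), 1), c(1, 1, 1, 0))
  d0 <- sqrt((train$x - 450)^2 + (train$y - 350)^2)
  sol <- unname(solve(A, c(gam(d0), 1)))

  pred <- ordinary_kriging_predict(train, v, model, target)
  expect_equal(pred$prediction, sum(sol[1:3] * v), tolerance = 1e-10)
  expect_equal(pred$variance, sum(sol[1:3] * gam(d0)) + sol[4],
               tolerance = 1e-10)
  expect_equal(as.numeric(attr(pred, "weights")), sol[1:3], tolerance = 1e-10)
})

test_that("kriging variance is positive away from data and the constraint is active", {
  pts <- rand_locations(30, seed = 19, width = 10000, height = 10000)
  set.seed(20)
  v <- rnorm(30, mean = 10)
  model <- variogram_model(0, 1.0, 4000)
  far <- data.frame(x = 5000 + 1, y = 5000 + 3)   # not a data point
  pred <- ordinary_kriging_predict(pts, v, model, far)
  expect_gt(pred$variance, 0)

  # dropping the unbiasedness constraint (simple-kriging solve) changes the
  # answer, so the Lagrange row is doing real work
  gam_mat <- matrix(0, 30, 30)
  d <- as.matrix(dist(pts))
  gam_mat <- spherical_gamma(d, model)
  g0 <- spherical_gamma(sqrt((pts$x - far$x)^2 + (pts$y - far$y)^2), model)
  w_unconstrained <- solve(gam_mat + diag(1e-10, 30), g0)
  pred_unconstrained <- sum(w_unconstrained * v)
  expect_false(isTRUE(all.equal(pred$prediction, pred_unconstrained,
                                tolerance = 1e-6)))
})

test_that("duplicate training points raise a conditioning error", {
  pts <- data.frame(x = c(0, 0, 500, 900), y = c(0, 0, 400, 100))
  expect_error(
    ordinary_kriging_predict(pts, 1:4, variogram_model(0, 1, 1000),
                             data.frame(x = 1, y = 1)),
    "share coordinates")
})

test_that("gridded prediction equals per-cell point prediction", {
  region <- region_spec(0, 0, 10000, 10000)
  pts <- rand_locations(30, seed = 22, width = 10000, height = 10000)
  set.seed(23)
  v <- rnorm(30)
  model <- variogram_model(0.2, 1.0, 4000)

  surf <- krige_grid(pts, v, model, region, cell_size_m = 500)
  expect_equal(dim(surf$values), c(20, 20))

  # row 1 is the northernmost row; spot-check two cells against direct calls
  for (cell in list(c(1, 1), c(12, 7))) {
    cx <- (cell[2] - 0.5) * 500
    cy <- 10000 - (cell[1] - 0.5) * 500
    direct <- ordinary_kriging_predict(pts, v, model,
                                       data.frame(x = cx, y = cy))
    expect_equal(surf$values[cell[1], cell[2]], direct$prediction,
                 tolerance = 1e-12)
  }

  # constant training values: weights summing to 1 force a constant surface
  flat <- krige_grid(pts, rep(7, 30), model, region, cell_size_m = 2000)
  expect_equal(as.numeric(flat$values), rep(7, 25), tolerance = 1e-8)
})

test_that("holdout split sizes follow the 90/10 protocol and errors are exact", {
  pts <- study_plots(n = 240, seed = 24)
  z <- sim_log_field(pts, 0.2, 1.0, 8000, seed = 24)
  model <- variogram_model(0.2, 1.0, 8000)
  cv <- cross_validate(pts, z, model, mode = "holdout",
                       holdout_fraction = 0.10, seed = 99)
  expect_equal(cv$n_train, 216L)
  expect_equal(cv$n_test, 24L)
  expect_equal(cv$me, mean(cv$residuals$residual))
  expect_equal(cv$rmse, sqrt(mean(cv$residuals$residual^2)))
  expect_gte(cv$rmse, abs(cv$me))

  # hand evaluation of the error formulas: obs [1,2,3], pred [1.5,2,2.5]
  res <- c(1, 2, 3) - c(1.5, 2, 2.5)
  expect_equal(mean(res), 0)
  expect_equal(sqrt(mean(res^2)), 0.40825, tolerance = 1e-5)
})

test_that("leave-one-out predicts each plot from the others", {
  pts <- rand_locations(15, seed = 26, width = 8000, height = 8000)
  set.seed(27)
  v <- rnorm(15)
  model <- variogram_model(0.1, 1.0, 4000)
  cv <- cross_validate(pts, v, model, mode = "loo")
  expect_equal(cv$n_test, 15L)
  expect_equal(cv$n_train, 14L)
  manual <- ordinary_kriging_predict(pts[-4, ], v[-4], model,
                                     pts[4, , drop = FALSE])
  expect_equal(cv$residuals$predicted[4], manual$prediction)
})

test_that("model selection ranks by RMSE with ME tiebreak toward zero", {
  mk <- function(me, rmse) {
    structure(list(me = me, rmse = rmse, n_train = 1L, n_test = 1L,
                   mode = "holdout", seed = 1L, residuals = NULL),
              class = "cv_report")
  }
  reports <- list(a = mk(0.5, 2), b = mk(0.1, 1), c = mk(-0.01, 1))
  expect_equal(rank_cv_reports(reports), c(3L, 2L, 1L))
})
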