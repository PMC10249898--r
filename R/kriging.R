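#' Ordinary kriging prediction
#'
#' Best linear unbiased prediction `Z(x0) = sum_i lambda_i Z(x_i)` with the
#' weights solving the ordinary-kriging system: the pairwise semivariance
#' matrix of the neighborhood, augmented with the unbiasedness row/column
#' (weights sum to 1) and a Lagrange multiplier. The kriging variance is
#' `sum_i lambda_i gamma(x_i, x0) + mu`. With a global neighborhood the
#' augmented matrix is factorized once for all targets.
#'
#' @param train_locations data.frame with columns `x`, `y` (>= 3 points, no
#'   duplicates).
#' @param train_values Numeric values aligned with `train_locations`.
#' @param model A fitted [variogram_model()].
#' @param target_locations data.frame with columns `x`, `y`.
#' @param neighborhood_size Number of nearest training points used per target;
#'   `NULL` (default) uses all of them.
#' @return A `kriging_prediction` data.frame with columns `x`, `y`,
#'   `prediction`, `variance`; attribute `weights` is the n_targets x n_train
#'   weight matrix (zero outside each target's neighborhood) and `lagrange`
#'   the per-target multiplier.
#' @export
ordinary_kriging_predict <- function(train_locations, train_values, model,
                                     target_locations,
                                     neighborhood_size = NULL) {
  assert_locations(train_locations, min_n = 3L)
  assert_locations(target_locations, min_n = 1L)
  stopifnot(inherits(model, "variogram_model"))
  n <- nrow(train_locations)
  if (length(train_values) != n) {
    stop("`train_values` must align with `train_locations`", call. = FALSE)
  }
  dup <- duplicated(train_locations[, c("x", "y")])
  if (any(dup)) {
    i <- which(dup)[1]
    j <- which(train_locations$x == train_locations$x[i] &
                 train_locations$y == train_locations$y[i])[1]
    stop(sprintf("singular kriging system: training points %d and %d share coordinates",
                 j, i), call. = FALSE)
  }
  if (is.null(neighborhood_size)) neighborhood_size <- n
  if (neighborhood_size < 3 || neighborhood_size > n) {
    stop("`neighborhood_size` must be in [3, n_train]", call. = FALSE)
  }

  m <- nrow(target_locations)
  d_tt <- pairwise_distances(train_locations)
  d_0t <- pairwise_distances(target_locations, train_locations)
  weights <- matrix(0, m, n)
  pred <- numeric(m)
  krig_var <- numeric(m)
  lagrange <- numeric(m)

  build_system <- function(idx) {
    k <- length(idx)
    A <- matrix(0, k + 1, k + 1)
    A[1:k, 1:k] <- spherical_gamma(d_tt[idx, idx, drop = FALSE], model)
    A[k + 1, 1:k] <- 1
    A[1:k, k + 1] <- 1
    A
  }

  if (neighborhood_size == n) {
    A <- build_system(seq_len(n))
    B <- rbind(t(spherical_gamma(d_0t, model)), rep(1, m))
    sol <- solve(A, B)                         # one factorization, m rhs
    weights <- t(sol[1:n, , drop = FALSE])
    lagrange <- sol[n + 1, ]
    pred <- as.numeric(weights %*% train_values)
    g0 <- spherical_gamma(d_0t, model)
    krig_var <- rowSums(weights * g0) + lagrange
  } else {
    for (t in seq_len(m)) {
      idx <- order(d_0t[t, ])[seq_len(neighborhood_size)]
      A <- build_system(idx)
      g0 <- spherical_gamma(d_0t[t, idx], model)
      sol <- solve(A, c(g0, 1))
      w <- sol[seq_along(idx)]
      weights[t, idx] <- w
      lagrange[t] <- sol[length(sol)]
      pred[t] <- sum(w * train_values[idx])
      krig_var[t] <- sum(w * g0) + lagrange[t]
    }
  }
  # clip tiny negative variances arising from round-off
  clipped <- krig_var < 0 & krig_var > -1e-8
  krig_var[clipped] <- 0
  out <- data.frame(x = target_locations$x, y = target_locations$y,
                    prediction = pred, variance = krig_var)
  structure(out, weights = weights, lagrange = lagrange,
            variance_clipped = any(clipped),
            class = c("kriging_prediction", "data.frame"))
}

#' Raster surface container
#'
#' @param origin_x,origin_y Lower-left corner of the grid, metres.
#' @param cell_size_m Cell side, metres.
#' @param values Matrix, `n_rows x n_cols`, row 1 = northernmost row.
#' @param nodata Marker written for missing cells.
#' @param transform `"log"` or `"raw"` tag recording the value scale.
#' @return A `raster_surface` list.
#' @export
raster_surface <- function(origin_x, origin_y, cell_size_m, values,
                           nodata = -9999, transform = "raw") {
  stopifnot(is.matrix(values))
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size_m = cell_size_m, n_rows = nrow(values),
                 n_cols = ncol(values), values = values, nodata = nodata,
                 transform = transform),
            class = "raster_surface")
}

#' Krige a regular grid over a region
#'
#' Predicts every cell center of a `cell_size_m` grid tiling `region` with
#' [ordinary_kriging_predict()], returning the prediction surface (row 1 =
#' northernmost row, as in ESRI ASCII rasters) and the matching kriging
#' variance surface.
#'
#' @param train_locations,train_values,model,neighborhood_size As in
#'   [ordinary_kriging_predict()].
#' @param region A [region_spec()].
#' @param cell_size_m Grid cell side, metres.
#' @param transform Scale tag stored on the surface (`"log"` or `"raw"`).
#' @return A [raster_surface()] with an extra `variance` matrix field.
#' @export
krige_grid <- function(train_locations, train_values, model, region,
                       cell_size_m, neighborhood_size = NULL,
                       transform = "raw") {
  stopifnot(inherits(region, "region_spec"))
  assert_scalar_number(cell_size_m, "cell_size_m", positive = TRUE)
  n_cols <- as.integer(ceiling(region$width_m / cell_size_m))
  n_rows <- as.integer(ceiling(region$height_m / cell_size_m))
  if (n_cols < 1 || n_rows < 1) stop("empty grid", call. = FALSE)

  cx <- region$origin_x + (seq_len(n_cols) - 0.5) * cell_size_m
  cy <- region$origin_y + (seq_len(n_rows) - 0.5) * cell_size_m
  # row-major north-to-south: row 1 is the top (largest y)
  centers <- expand.grid(x = cx, y = rev(cy))[, c("x", "y")]
  pred <- ordinary_kriging_predict(train_locations, train_values, model,
                                   centers, neighborhood_size)
  surf <- raster_surface(region$origin_x, region$origin_y, cell_size_m,
                         matrix(pred$prediction, n_rows, n_cols, byrow = TRUE),
                         transform = transform)
  surf$variance <- matrix(pred$variance, n_rows, n_cols, byrow = TRUE)
  surf
}

#' Cross-validate kriging predictions
#'
#' Either a seeded hold-out split (`n_train = round(n * (1 - holdout_fraction))`
#' plots interpolate the remaining validation plots) or leave-one-out (each
#' plot predicted from all others in turn). Reports the mean error
#' `ME = mean(x_i - xhat_i)` (systematic bias) and the root-mean-square error
#' `RMSE = sqrt(mean((x_i - xhat_i)^2))`; residuals are observed minus
#' predicted. As ME approaches 0 and RMSE shrinks, prediction accuracy
#' improves.
#'
#' @param locations data.frame with columns `x`, `y`.
#' @param values Observed values aligned with `locations` (already on the
#'   scale being kriged, e.g. log-transformed).
#' @param model A fitted [variogram_model()].
#' @param mode `"holdout"` or `"loo"`.
#' @param holdout_fraction Validation fraction in `(0, 1)` for `"holdout"`.
#' @param seed Split seed (recorded in the report).
#' @param neighborhood_size Passed to [ordinary_kriging_predict()].
#' @return A `cv_report` list: `me`, `rmse`, `n_train`, `n_test`, `mode`,
#'   `seed`, and `residuals` (data.frame `index`, `observed`, `predicted`,
#'   `residual`).
#' @export
cross_validate <- function(locations, values, model,
                           mode = c("holdout", "loo"),
                           holdout_fraction = 0.1, seed = 1L,
                           neighborhood_size = NULL) {
  mode <- match.arg(mode)
  assert_locations(locations, min_n = 10L)
  n <- nrow(locations)
  stopifnot(length(values) == n, inherits(model, "variogram_model"))

  if (mode == "holdout") {
    if (holdout_fraction <= 0 || holdout_fraction >= 1) {
      stop("`holdout_fraction` must be in (0, 1)", call. = FALSE)
    }
    n_train <- round(n * (1 - holdout_fraction))
    train_idx <- with_seed(seed, sample(n, n_train))
    test_idx <- setdiff(seq_len(n), train_idx)
    pred <- ordinary_kriging_predict(locations[train_idx, ], values[train_idx],
                                     model, locations[test_idx, ],
                                     neighborhood_size)
    predicted <- pred$prediction
  } else {
    test_idx <- seq_len(n)
    n_train <- n - 1L
    predicted <- vapply(seq_len(n), function(i) {
      ordinary_kriging_predict(locations[-i, ], values[-i], model,
                               locations[i, , drop = FALSE],
                               neighborhood_size)$prediction
    }, numeric(1))
  }
  observed <- values[test_idx]
  residual <- observed - predicted
  structure(list(
    me = mean(residual),
    rmse = sqrt(mean(residual^2)),
    n_train = as.integer(n_train),
    n_test = length(test_idx),
    mode = mode,
    seed = as.integer(seed),
    residuals = data.frame(index = test_idx, observed = observed,
                           predicted = predicted, residual = residual)
  ), class = "cv_report")
}

#' Rank cross-validation reports by prediction accuracy
#'
#' Orders candidate models by RMSE (smaller wins), breaking ties toward the
#' mean error closest to 0.
#'
#' @param reports List of [cross_validate()] reports.
#' @return Integer permutation ordering `reports` best-first.
#' @export
rank_cv_reports <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "cv_report")))
  rmse <- vapply(reports, `[[`, numeric(1), "rmse")
  abs_me <- abs(vapply(reports, `[[`, numeric(1), "me"))
  order(rmse, abs_me)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("kriging cross-validation (%s, seed %d): n_train = %d, n_test = %d\n",
              x$mode, x$seed, x$n_train, x$n_test))
  cat(sprintf("  ME = %.5f, RMSE = %.5f\n", x$me, x$rmse))
  invisible(x)
}

#' @export
print.raster_surface <- function(x, ...) {
  cat(sprintf("raster surface: %d x %d cells of %.0f m (%s scale)\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$transform))
  invisible(x)
}
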