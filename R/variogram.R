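#' Spherical variogram model
#'
#' Holds the nugget `Co` (variance at the y-intercept: measurement error and
#' micro-scale variation), total sill `C` (the semivariance plateau) and range
#' `a` (distance beyond which pairs are effectively uncorrelated) of a
#' spherical semivariogram.
#'
#' @param nugget Nugget `Co`, `>= 0`, variance units.
#' @param sill Total sill `C >= Co`, variance units.
#' @param range Range `a > 0`, metres.
#' @return A `variogram_model` list.
#' @export
#' @examples
#' variogram_model(nugget = 0.2, sill = 1, range = 8000)
variogram_model <- function(nugget, sill, range) {
  assert_scalar_number(nugget, "nugget")
  assert_scalar_number(sill, "sill")
  assert_scalar_number(range, "range", positive = TRUE)
  if (nugget < 0 || sill < nugget) {
    stop("need 0 <= nugget <= sill", call. = FALSE)
  }
  structure(list(nugget = nugget, sill = sill, range = range,
                 form = "spherical"),
            class = "variogram_model")
}

#' Spherical semivariogram function
#'
#' `gamma(h) = Co + (C - Co) (1.5 h/a - 0.5 (h/a)^3)` for `0 < h <= a`,
#' `gamma(h) = C` beyond the range, and `gamma(0) = 0` exactly (the nugget is
#' a discontinuity at the origin, not a value at distance zero).
#'
#' @param h Distances, metres (vectorized).
#' @param model A [variogram_model()].
#' @return Semivariances at `h`.
#' @export
spherical_gamma <- function(h, model) {
  stopifnot(inherits(model, "variogram_model"))
  r <- pmin(h / model$range, 1)
  g <- model$nugget + (model$sill - model$nugget) * (1.5 * r - 0.5 * r^3)
  g[h == 0] <- 0
  g
}

#' Average nearest-neighbor distance
#'
#' Mean over all points of the Euclidean distance to each point's nearest
#' other point; the standard rule of thumb for a semivariogram lag step on
#' irregular samples, since each lag then holds at least a few pairs.
#'
#' @param locations data.frame with columns `x`, `y`; at least 2 points.
#' @return Mean nearest-neighbor distance, metres.
#' @export
average_nearest_neighbor_distance <- function(locations) {
  assert_locations(locations, min_n = 2L)
  d <- pairwise_distances(locations)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  if (any(nn == 0)) {
    warning(sprintf("%d point(s) share coordinates with another point; %s",
                    sum(nn == 0),
                    "their nearest-neighbor distance is 0"), call. = FALSE)
  }
  mean(nn)
}

#' Choose the semivariogram lag structure
#'
#' Sets the lag step to the average nearest-neighbor distance and the maximum
#' separation to the largest pairwise distance; the number of lags is chosen
#' so that `lag_step * n_lags` is about half the maximum separation
#' (`n_lags = round(max_dist / 2 / lag_step)`), overridable.
#'
#' @param locations data.frame with columns `x`, `y`.
#' @param n_lags Optional override of the half-max rule.
#' @return List with `lag_step`, `n_lags`, `max_dist` (all metres/counts).
#' @export
lag_structure <- function(locations, n_lags = NULL) {
  assert_locations(locations, min_n = 2L)
  d <- pairwise_distances(locations)
  max_dist <- max(d)
  if (max_dist == 0) {
    stop("degenerate geometry: all points collocated", call. = FALSE)
  }
  lag_step <- average_nearest_neighbor_distance(locations)
  if (is.null(n_lags)) {
    n_lags <- round(max_dist / 2 / lag_step)
  }
  list(lag_step = lag_step, n_lags = as.integer(n_lags), max_dist = max_dist)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins every unordered point pair by separation into
#' `[k * lag_step, (k + 1) * lag_step)` intervals and computes per bin
#' `gamma(h) = (1 / 2N(h)) * sum (x_i - x_j)^2` over the `N(h)` pairs in the
#' bin. Pairs separated by more than `max_dist` are excluded; empty bins are
#' reported with `gamma = NA`.
#'
#' @param locations data.frame with columns `x`, `y`.
#' @param values Numeric values aligned with `locations`.
#' @param lag_step Bin width, metres.
#' @param n_lags Number of bins.
#' @param max_dist Maximum pair separation retained, metres; defaults to
#'   `n_lags * lag_step`.
#' @return An `empirical_variogram` data.frame with columns `lag` (bin
#'   midpoint), `dist_avg` (mean pair separation in the bin), `gamma`,
#'   `n_pairs`; attributes `lag_step`, `n_lags`, `max_dist`.
#' @export
empirical_semivariogram <- function(locations, values, lag_step, n_lags,
                                    max_dist = n_lags * lag_step) {
  assert_locations(locations, min_n = 2L)
  if (length(values) != nrow(locations)) {
    stop("`values` must align with `locations`", call. = FALSE)
  }
  assert_scalar_number(lag_step, "lag_step", positive = TRUE)
  assert_scalar_number(max_dist, "max_dist", positive = TRUE)
  n_lags <- as.integer(n_lags)
  stopifnot(n_lags >= 1)

  dmat <- pairwise_distances(locations)
  keep <- upper.tri(dmat)                       # unordered pairs once
  d <- dmat[keep]
  sqdiff <- (outer(values, values, "-")^2)[keep]
  inside <- d <= max_dist & d < n_lags * lag_step
  if (!any(inside)) {
    stop("empty variogram: all pairs beyond max_dist", call. = FALSE)
  }
  d <- d[inside]
  sqdiff <- sqdiff[inside]
  bin <- floor(d / lag_step) + 1L               # [k*h, (k+1)*h) -> k+1

  n_pairs <- tabulate(bin, nbins = n_lags)
  sum_sq <- vapply(seq_len(n_lags),
                   function(k) sum(sqdiff[bin == k]), numeric(1))
  sum_d <- vapply(seq_len(n_lags),
                  function(k) sum(d[bin == k]), numeric(1))
  gamma <- ifelse(n_pairs > 0, sum_sq / (2 * n_pairs), NA_real_)
  out <- data.frame(
    lag = (seq_len(n_lags) - 0.5) * lag_step,
    dist_avg = ifelse(n_pairs > 0, sum_d / n_pairs, NA_real_),
    gamma = gamma,
    n_pairs = n_pairs
  )
  structure(out, lag_step = lag_step, n_lags = n_lags, max_dist = max_dist,
            class = c("empirical_variogram", "data.frame"))
}

#' Fit a spherical model to an empirical semivariogram
#'
#' Weighted least squares over populated lags, minimizing
#' `sum_k w_k (gamma_k - gamma_model(h_k))^2` with Cressie-style weights
#' `w_k = N(h_k) / gamma_model(h_k)^2` (default) or plain pair counts
#' `w_k = N(h_k)`. The Cressie weights emphasise the short, low-semivariance
#' lags that determine the nugget, which plain pair counts leave dominated by
#' the many long-range pairs. The fit is a bounded
#' multi-start local optimization (`L-BFGS-B` from a fixed start grid over
#' nugget fraction, partial sill and range), so it is deterministic; the
#' constraints `0 <= Co <= C` and `0 < a <= max_dist` are enforced by the
#' parameterization and bounds. Lags are placed at each bin's mean pair
#' separation.
#'
#' @param emp An [empirical_semivariogram()] result (or any data.frame with
#'   `lag`/`dist_avg`, `gamma`, `n_pairs`); at least 4 populated lags.
#' @param weights `"cressie"` (default) or `"npairs"`.
#' @return A [variogram_model()] with extra fields `objective`, `weights`,
#'   `n_lags_used`.
#' @export
fit_spherical_model <- function(emp, weights = c("cressie", "npairs")) {
  weights <- match.arg(weights)
  ok <- !is.na(emp$gamma) & emp$n_pairs > 0
  if (sum(ok) < 4) {
    stop(sprintf("need >= 4 populated lags, got %d", sum(ok)), call. = FALSE)
  }
  h <- if (!is.null(emp$dist_avg)) emp$dist_avg[ok] else emp$lag[ok]
  g <- emp$gamma[ok]
  npairs <- emp$n_pairs[ok]
  hmax <- max(h, attr(emp, "max_dist") %||% max(h))
  gmax <- max(g)
  if (gmax == 0) {
    # constant field: flat zero variogram, degenerate but well-defined
    return(structure(c(variogram_model(0, 0 + 1e-12, hmax),
                       list(objective = 0, weights = weights,
                            n_lags_used = sum(ok))),
                     class = "variogram_model"))
  }

  sph <- function(hh, co, c1, a) {
    r <- pmin(hh / a, 1)
    co + c1 * (1.5 * r - 0.5 * r^3)
  }
  obj <- function(par) {
    gm <- sph(h, par[1], par[2], par[3])
    w <- if (weights == "npairs") npairs else npairs / pmax(gm, 1e-12)^2
    sum(w * (g - gm)^2)
  }

  starts <- expand.grid(co = c(0, 0.25, 0.5) * gmax,
                        c1 = c(0.5, 1) * gmax,
                        a = c(0.2, 0.4, 0.7, 1) * hmax)
  # ranges below the smallest sampled lag are unidentifiable (any nugget
  # split fits equally well), so the range is bounded by [min(h), max]
  lower <- c(0, 0, min(h))
  upper <- c(2 * gmax, 4 * gmax, hmax)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmax(as.numeric(starts[i, ]), lower), obj,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("spherical fit failed to converge from every start", call. = FALSE)
  }
  polish <- tryCatch(
    stats::nlminb(best$par, obj, lower = lower, upper = upper,
                  control = list(rel.tol = 1e-15, x.tol = 1e-15,
                                 iter.max = 1000)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$objective <= best$value) {
    best <- list(par = polish$par, value = polish$objective)
  }
  model <- variogram_model(nugget = best$par[1],
                           sill = best$par[1] + best$par[2],
                           range = best$par[3])
  model$objective <- best$value
  model$weights <- weights
  model$n_lags_used <- sum(ok)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify spatial dependence from the nugget-to-sill ratio
#'
#' `Co/C` expressed as a percentage classifies the strength of spatial
#' correlation: `< 25%` strong, `25--75%` moderate, `> 75%` weak.
#'
#' @param model A [variogram_model()] with `sill > 0`.
#' @return A `spatial_dependence_class` list with `nugget_ratio_percent` and
#'   `label` (`"strong"`, `"moderate"` or `"weak"`).
#' @export
#' @examples
#' classify_spatial_dependence(variogram_model(0.2131, 1, 8000))
classify_spatial_dependence <- function(model) {
  stopifnot(inherits(model, "variogram_model"))
  if (model$sill <= 0) {
    stop("degenerate model: sill must be > 0 to classify", call. = FALSE)
  }
  ratio <- 100 * model$nugget / model$sill
  label <- if (ratio < 25) "strong" else if (ratio <= 75) "moderate" else "weak"
  structure(list(nugget_ratio_percent = ratio, label = label),
            class = "spatial_dependence_class")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("spherical variogram model: Co = %.4g, C = %.4g, a = %.1f m\n",
              x$nugget, x$sill, x$range))
  if (x$sill > 0) {
    cls <- classify_spatial_dependence(x)
    cat(sprintf("  Co/C = %.2f%% (%s spatial dependence)\n",
                cls$nugget_ratio_percent, cls$label))
  }
  invisible(x)
}

#' @export
print.spatial_dependence_class <- function(x, ...) {
  cat(sprintf("Co/C = %.2f%% -> %s spatial dependence\n",
              x$nugget_ratio_percent, x$label))
  invisible(x)
}
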