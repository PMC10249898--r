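#' Specify a rectangular study region
#'
#' The study region is a rectangle in projected planar coordinates (metres,
#' x east / y north). All synthetic sampling, kriging grids and zonal driver
#' layers are defined relative to a region.
#'
#' @param origin_x,origin_y Lower-left corner, metres.
#' @param width_m,height_m Extent, metres; both must be positive.
#' @return A `region_spec` list.
#' @export
#' @examples
#' region_spec(0, 0, 30000, 35000)
region_spec <- function(origin_x = 0, origin_y = 0, width_m, height_m) {
  assert_scalar_number(origin_x, "origin_x")
  assert_scalar_number(origin_y, "origin_y")
  assert_scalar_number(width_m, "width_m", positive = TRUE)
  assert_scalar_number(height_m, "height_m", positive = TRUE)
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 width_m = width_m, height_m = height_m),
            class = "region_spec")
}

#' Specify a grid-random sampling design
#'
#' Grid-random sampling tiles the region into square cells and places at most
#' one uniformly located plot per cell, balancing randomness against even
#' spatial coverage. A seeded random subset of cells is excluded first,
#' emulating field plots dropped as inaccessible or redundant.
#'
#' @param cell_size_m Cell side, metres.
#' @param n_target Number of plots to place.
#' @param exclusion_fraction Fraction of cells removed before sampling, in
#'   `[0, 1)`.
#' @param seed Integer seed for cell exclusion, cell selection and in-cell
#'   placement.
#' @return A `sampling_design` list.
#' @export
sampling_design <- function(cell_size_m, n_target, exclusion_fraction = 0,
                            seed = 1L) {
  assert_scalar_number(cell_size_m, "cell_size_m", positive = TRUE)
  assert_scalar_number(n_target, "n_target")
  if (n_target < 1 || n_target != round(n_target)) {
    stop("`n_target` must be a positive integer", call. = FALSE)
  }
  assert_scalar_number(exclusion_fraction, "exclusion_fraction")
  if (exclusion_fraction < 0 || exclusion_fraction >= 1) {
    stop("`exclusion_fraction` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(cell_size_m = cell_size_m, n_target = as.integer(n_target),
                 exclusion_fraction = exclusion_fraction,
                 seed = as.integer(seed)),
            class = "sampling_design")
}

#' Number of grid cells a region tiles into
#'
#' @param region A [region_spec()].
#' @param cell_size_m Cell side, metres.
#' @return Named integer vector with `nx`, `ny` and `n_cells`.
#' @export
grid_cell_counts <- function(region, cell_size_m) {
  nx <- as.integer(ceiling(region$width_m / cell_size_m))
  ny <- as.integer(ceiling(region$height_m / cell_size_m))
  c(nx = nx, ny = ny, n_cells = nx * ny)
}

#' Draw a grid-random plot sample
#'
#' Tiles `region` into `ceiling(width / cell) * ceiling(height / cell)` cells,
#' excludes `round(exclusion_fraction * n_cells)` randomly chosen cells, then
#' selects `n_target` of the remaining cells and places one point uniformly
#' inside each (clipped to the region where an edge cell overhangs it).
#' Deterministic given `design$seed`.
#'
#' @param region A [region_spec()].
#' @param design A [sampling_design()].
#' @return A data.frame with columns `cell`, `x`, `y`; attribute `n_cells`
#'   records the tiling size.
#' @export
#' @examples
#' region <- region_spec(0, 0, 30000, 35000)
#' design <- sampling_design(2500, n_target = 120, exclusion_fraction = 0.2)
#' plots <- grid_random_sample(region, design)
#' nrow(plots)
grid_random_sample <- function(region, design) {
  stopifnot(inherits(region, "region_spec"), inherits(design, "sampling_design"))
  counts <- grid_cell_counts(region, design$cell_size_m)
  nx <- counts[["nx"]]
  n_cells <- counts[["n_cells"]]
  n_excluded <- round(design$exclusion_fraction * n_cells)

  with_seed(design$seed, {
    available <- seq_len(n_cells)
    if (n_excluded > 0) {
      available <- setdiff(available, sample(n_cells, n_excluded))
    }
    if (design$n_target > length(available)) {
      stop(sprintf(
        "n_target (%d) exceeds the %d cells available after excluding %d of %d",
        design$n_target, length(available), n_excluded, n_cells), call. = FALSE)
    }
    chosen <- sample(available, design$n_target)
    ix <- (chosen - 1L) %% nx          # 0-based column
    iy <- (chosen - 1L) %/% nx         # 0-based row
    cs <- design$cell_size_m
    # uniform inside the cell, truncated to the region for overhanging cells
    x_lo <- region$origin_x + ix * cs
    x_hi <- pmin(x_lo + cs, region$origin_x + region$width_m)
    y_lo <- region$origin_y + iy * cs
    y_hi <- pmin(y_lo + cs, region$origin_y + region$height_m)
    out <- data.frame(
      cell = chosen,
      x = x_lo + stats::runif(design$n_target) * (x_hi - x_lo),
      y = y_lo + stats::runif(design$n_target) * (y_hi - y_lo)
    )
    attr(out, "n_cells") <- n_cells
    attr(out, "nx") <- nx
    attr(out, "ny") <- counts[["ny"]]
    out
  })
}

#' Spherical covariance function
#'
#' Covariance implied by a spherical variogram model with partial sill
#' `sill - nugget` and range `a`: `C(h) = (C - Co) (1 - 1.5 h/a + 0.5 (h/a)^3)`
#' for `h < a` and 0 beyond. The nugget is not part of the continuous
#' covariance; it is realised as independent per-plot noise.
#'
#' @param h Distances, metres.
#' @param model A [variogram_model()].
#' @return Covariances at `h`.
#' @export
spherical_covariance <- function(h, model) {
  stopifnot(inherits(model, "variogram_model"))
  partial_sill <- model$sill - model$nugget
  r <- pmin(h / model$range, 1)
  partial_sill * (1 - 1.5 * r + 0.5 * r^3)
}

#' Specify a synthetic ecosystem-service field
#'
#' Field values are lognormal: log-scale values are drawn from a Gaussian
#' random field with spherical spatial covariance (plus nugget noise) around
#' `mean_log`, then exponentiated. This mirrors service measurements that are
#' normally distributed only after log transformation.
#'
#' @param model A [variogram_model()] describing the log-scale field.
#' @param mean_log Log-scale mean.
#' @param seed Integer seed.
#' @param service_name Label used for the generated column.
#' @return A `synthetic_field_spec` list.
#' @export
synthetic_field_spec <- function(model, mean_log = 0, seed = 1L,
                                 service_name = "service") {
  stopifnot(inherits(model, "variogram_model"))
  assert_scalar_number(mean_log, "mean_log")
  structure(list(model = model, mean_log = mean_log, seed = as.integer(seed),
                 service_name = as.character(service_name)),
            class = "synthetic_field_spec")
}

#' Simulate a spatially autocorrelated ecosystem-service column
#'
#' Draws log-scale values from a multivariate normal with mean
#' `spec$mean_log` and covariance given by the spherical model: structured
#' covariance [spherical_covariance()] between plots plus independent nugget
#' noise of variance `Co` at each plot. Returns the exponentiated values, so
#' every service value is positive. Deterministic given `spec$seed`.
#'
#' @param locations data.frame with columns `x`, `y`.
#' @param spec A [synthetic_field_spec()].
#' @return Numeric vector of ES values, one per location.
#' @export
simulate_es_field <- function(locations, spec) {
  assert_locations(locations, min_n = 1L)
  stopifnot(inherits(spec, "synthetic_field_spec"))
  n <- nrow(locations)
  model <- spec$model
  partial_sill <- model$sill - model$nugget

  with_seed(spec$seed, {
    structured <- numeric(n)
    if (partial_sill > 0) {
      sigma <- spherical_covariance(pairwise_distances(locations), model)
      L <- NULL
      jitter <- partial_sill * 1e-10
      for (k in 0:3) {
        L <- tryCatch(chol(sigma + diag(jitter * 10^k, n)), error = function(e) NULL)
        if (!is.null(L)) break
      }
      if (is.null(L)) {
        stop("spherical covariance matrix is not positive definite after jitter",
             call. = FALSE)
      }
      structured <- drop(crossprod(L, stats::rnorm(n)))
    }
    nugget_noise <- if (model$nugget > 0) {
      stats::rnorm(n, sd = sqrt(model$nugget))
    } else {
      numeric(n)
    }
    exp(spec$mean_log + structured + nugget_noise)
  })
}

#' Specify a zonal driver layer
#'
#' @param n_zones Number of contiguous vertical zones (>= 2).
#' @param zone_effect_sd Scale of per-zone coupling to the field, log-scale sd.
#' @param noise_sd Residual sd of the continuous covariate.
#' @param seed Integer seed.
#' @return A `driver_spec` list.
#' @export
driver_spec <- function(n_zones, zone_effect_sd, noise_sd, seed = 1L) {
  if (!is.numeric(n_zones) || n_zones < 2 || n_zones != round(n_zones)) {
    stop("`n_zones` must be an integer >= 2", call. = FALSE)
  }
  assert_scalar_number(zone_effect_sd, "zone_effect_sd")
  assert_scalar_number(noise_sd, "noise_sd")
  if (zone_effect_sd < 0 || noise_sd < 0) {
    stop("`zone_effect_sd` and `noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(n_zones = as.integer(n_zones), zone_effect_sd = zone_effect_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "driver_spec")
}

#' Simulate a zonal categorical driver and a coupled continuous covariate
#'
#' Partitions the sampled extent into `n_zones` contiguous vertical bands and
#' assigns each plot its band id. Each zone receives a seeded coupling
#' strength drawn as `|Normal(0, zone_effect_sd)|`; the continuous covariate
#' at a plot is its zone's coupling strength times the plot's standardized
#' log-field value, plus `Normal(0, noise_sd)` noise. With
#' `zone_effect_sd = 0` the covariate is pure noise and carries no information
#' about the field; with `zone_effect_sd >> noise_sd` the discretized
#' covariate explains most of the field's variance, so the driver's
#' geographical-detector q is tunable. Coupling strengths are nonnegative so
#' that the covariate is monotone in the field within every zone; signed
#' couplings would fold high and low field values into the same covariate
#' class and cap the attainable q well below its intended ceiling.
#'
#' @param locations data.frame with columns `x`, `y`.
#' @param field_log_values Log-scale field values aligned with `locations`.
#' @param spec A [driver_spec()].
#' @return data.frame with columns `zone` (integer in `1..n_zones`) and
#'   `covariate`.
#' @export
simulate_driver_layers <- function(locations, field_log_values, spec) {
  assert_locations(locations, min_n = 1L)
  stopifnot(inherits(spec, "driver_spec"))
  n <- nrow(locations)
  if (length(field_log_values) != n) {
    stop("`field_log_values` must align with `locations`", call. = FALSE)
  }
  if (n < spec$n_zones) {
    stop(sprintf("fewer plots (%d) than zones (%d)", n, spec$n_zones),
         call. = FALSE)
  }
  xr <- range(locations$x)
  breaks <- seq(xr[1], xr[2], length.out = spec$n_zones + 1)
  zone <- findInterval(locations$x, breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  f_sd <- stats::sd(field_log_values)
  f_std <- if (is.na(f_sd) || f_sd == 0) {
    rep(0, n)
  } else {
    (field_log_values - mean(field_log_values)) / f_sd
  }
  with_seed(spec$seed, {
    coupling <- abs(stats::rnorm(spec$n_zones, 0, spec$zone_effect_sd))
    covariate <- coupling[zone] * f_std + stats::rnorm(n, 0, spec$noise_sd)
    data.frame(zone = as.integer(zone), covariate = covariate)
  })
}

#' Build a complete synthetic plot table
#'
#' Convenience wrapper tying the synthetic module together: samples plot
#' locations by grid-random sampling, simulates one lognormal service column
#' per field spec, and (optionally) attaches zonal driver layers coupled to
#' the first service's log values.
#'
#' @param region A [region_spec()].
#' @param design A [sampling_design()].
#' @param field_specs List of [synthetic_field_spec()], one per service.
#' @param driver_specs Optional named list of [driver_spec()]; each name
#'   `nm` contributes columns `nm_zone` and `nm_cov`.
#' @return A plot table data.frame (`plot_id`, `x`, `y`, one column per
#'   service, driver columns) with attribute `services` naming the service
#'   columns and `drivers` naming driver columns.
#' @export
synthesize_plot_table <- function(region, design, field_specs,
                                  driver_specs = NULL) {
  stopifnot(length(field_specs) >= 1)
  pts <- grid_random_sample(region, design)
  table <- data.frame(plot_id = sprintf("plot_%03d", seq_len(nrow(pts))),
                      x = pts$x, y = pts$y)
  services <- character(0)
  first_log <- NULL
  for (fs in field_specs) {
    vals <- simulate_es_field(pts, fs)
    table[[fs$service_name]] <- vals
    services <- c(services, fs$service_name)
    if (is.null(first_log)) first_log <- log(vals)
  }
  drivers <- character(0)
  if (!is.null(driver_specs)) {
    for (nm in names(driver_specs)) {
      dl <- simulate_driver_layers(pts, first_log, driver_specs[[nm]])
      table[[paste0(nm, "_zone")]] <- dl$zone
      table[[paste0(nm, "_cov")]] <- dl$covariate
      drivers <- c(drivers, paste0(nm, "_zone"), paste0(nm, "_cov"))
    }
  }
  attr(table, "services") <- services
  attr(table, "drivers") <- drivers
  table
}
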