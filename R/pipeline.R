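#' Default pipeline configuration
#'
#' A fully synthetic configuration emulating a grid-random plot survey of an
#' urban forest: a 30 km x 35 km region tiled by 2500 m cells, 120 plots
#' kept after excluding 20% of cells, three lognormal services with spherical
#' spatial structure, and two zonal drivers (one strongly coupled to the
#' first service, one pure noise). Every field of the returned list can be
#' overridden before passing it to [run_pipeline()].
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      region = list(origin_x = 0, origin_y = 0, width_m = 30000,
                    height_m = 35000),
      design = list(cell_size_m = 2500, n_target = 120,
                    exclusion_fraction = 0.2),
      fields = list(
        list(service_name = "carbon_storage", nugget = 0.2, sill = 1.0,
             range = 8000, mean_log = 4.0),
        list(service_name = "avoided_runoff", nugget = 0.3, sill = 1.0,
             range = 8000, mean_log = 2.0),
        list(service_name = "pollution_removal", nugget = 0.6, sill = 1.0,
             range = 8000, mean_log = 1.0)
      ),
      drivers = list(
        population = list(n_zones = 5, zone_effect_sd = 2, noise_sd = 0.2),
        gdp = list(n_zones = 5, zone_effect_sd = 0, noise_sd = 1)
      )
    ),
    input = NULL,
    composite_services = NULL,      # default: all services
    target_service = NULL,          # default: first service
    transform = "log",
    variogram = list(n_lags = NULL, weights = "cressie"),
    kriging = list(cell_size_m = 1500, neighborhood = NULL,
                   cv_mode = "holdout", holdout_fraction = 0.1,
                   back_transform = FALSE),
    hotspot = list(d = NULL, include_self = TRUE),
    geodetector = list(drivers = NULL, k = 5, p_threshold = 0.1)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_pipeline_config()], so a
#' config file only needs to state what differs from the defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
load_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(default_pipeline_config(user$seed %||% 1L), user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

synthesize_from_config <- function(config) {
  syn <- config$synthetic
  region <- region_spec(syn$region$origin_x, syn$region$origin_y,
                        syn$region$width_m, syn$region$height_m)
  design <- sampling_design(syn$design$cell_size_m, syn$design$n_target,
                            syn$design$exclusion_fraction %||% 0,
                            seed = config$seed)
  field_specs <- lapply(seq_along(syn$fields), function(i) {
    f <- syn$fields[[i]]
    synthetic_field_spec(
      variogram_model(f$nugget, f$sill, f$range),
      mean_log = f$mean_log %||% 0,
      seed = config$seed + i,
      service_name = f$service_name)
  })
  driver_specs <- NULL
  if (length(syn$drivers) > 0) {
    driver_specs <- lapply(seq_along(syn$drivers), function(i) {
      d <- syn$drivers[[i]]
      driver_spec(d$n_zones, d$zone_effect_sd, d$noise_sd,
                  seed = config$seed + 100 + i)
    })
    names(driver_specs) <- names(syn$drivers)
  }
  list(table = synthesize_plot_table(region, design, field_specs,
                                     driver_specs),
       region = region)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full spatial-heterogeneity pipeline
#'
#' Executes, in order: plot acquisition (synthetic generation or CSV read),
#' distribution diagnostics, composite ES, semivariogram fit and
#' spatial-dependence classification, kriging grid and cross-validation,
#' Gi* hotspot detection, and geographical-detector driver analysis. All
#' artifacts are written under `output_dir` together with a JSON manifest
#' recording the configuration, seeds, package version and an MD5 hash of
#' every file. Deterministic given `config$seed`.
#'
#' @param config A configuration list ([default_pipeline_config()],
#'   [load_pipeline_config()]), or a path to a YAML config.
#' @param output_dir Output directory, created if needed; `NULL` skips all
#'   file output.
#' @return Invisibly, a list with elements `table`, `diagnostics`,
#'   `composite`, `variogram` (empirical, model, class), `surface`,
#'   `cv`, `hotspot`, `geodetector`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  message("pipeline: starting (seed ", config$seed, ")")

  # --- acquire plots ---------------------------------------------------------
  region <- NULL
  if (!is.null(config$input)) {
    table <- pipeline_stage("read", read_plot_table(config$input))
    region <- region_spec(min(table$x), min(table$y),
                          diff(range(table$x)), diff(range(table$y)))
  } else {
    syn <- pipeline_stage("synthetic", synthesize_from_config(config))
    table <- syn$table
    region <- syn$region
  }
  services <- attr(table, "services") %||%
    setdiff(names(table), c("plot_id", "x", "y"))
  drivers <- config$geodetector$drivers %||% attr(table, "drivers")
  message("pipeline: ", nrow(table), " plots, services: ",
          paste(services, collapse = ", "))

  # --- diagnostics -----------------------------------------------------------
  diagnostics <- pipeline_stage("diagnostics", do.call(rbind, lapply(
    services, function(nm) {
      raw <- distribution_diagnostics(table[[nm]], "none")
      lg <- distribution_diagnostics(table[[nm]], "log")
      data.frame(service = nm, n = raw$n,
                 skewness_raw = raw$skewness, kurtosis_raw = raw$kurtosis,
                 skewness_log = lg$skewness, kurtosis_log = lg$kurtosis)
    })))

  # --- composite -------------------------------------------------------------
  comp_services <- config$composite_services %||% services
  composite <- pipeline_stage("composite", composite_es(table, comp_services))
  table$composite_es <- composite$composite

  # --- variogram -------------------------------------------------------------
  target <- config$target_service %||% services[1]
  transform <- config$transform %||% "log"
  z <- if (transform == "log") log(table[[target]]) else table[[target]]
  vario <- pipeline_stage("variogram", {
    lags <- lag_structure(table, n_lags = config$variogram$n_lags)
    emp <- empirical_semivariogram(table, z, lags$lag_step, lags$n_lags,
                                   lags$max_dist)
    model <- fit_spherical_model(emp, weights = config$variogram$weights)
    list(lags = lags, empirical = emp, model = model,
         class = classify_spatial_dependence(model))
  })
  message(sprintf("pipeline: variogram Co/C = %.1f%% (%s), a = %.0f m",
                  vario$class$nugget_ratio_percent, vario$class$label,
                  vario$model$range))

  # --- kriging ---------------------------------------------------------------
  kcfg <- config$kriging
  surface <- pipeline_stage("kriging", {
    s <- krige_grid(table, z, vario$model, region, kcfg$cell_size_m,
                    neighborhood_size = kcfg$neighborhood,
                    transform = transform)
    if (isTRUE(kcfg$back_transform) && transform == "log") {
      s$values <- exp(s$values + s$variance / 2)   # lognormal back-transform
      s$transform <- "raw"
    }
    s
  })
  cv <- pipeline_stage("cross-validation",
    cross_validate(table, z, vario$model, mode = kcfg$cv_mode,
                   holdout_fraction = kcfg$holdout_fraction,
                   seed = config$seed + 200,
                   neighborhood_size = kcfg$neighborhood))
  message(sprintf("pipeline: cross-validation ME = %.4f, RMSE = %.4f",
                  cv$me, cv$rmse))

  # --- hotspot ---------------------------------------------------------------
  hs_d <- config$hotspot$d %||% (2 * vario$lags$lag_step)
  hotspot <- pipeline_stage("hotspot", {
    w <- suppressWarnings(distance_band_weights(
      table, hs_d, include_self = config$hotspot$include_self %||% TRUE))
    getis_ord_gi_star(table[[target]], w)
  })
  hotspot$plot_id <- table$plot_id

  # --- geodetector -----------------------------------------------------------
  geodetector <- NULL
  if (length(drivers) > 0) {
    geodetector <- pipeline_stage("geodetector",
      run_geodetector(table, target, drivers,
                      k = config$geodetector$k %||% 5,
                      p_threshold = config$geodetector$p_threshold %||% 0.1))
  }

  # --- artifacts -------------------------------------------------------------
  manifest <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    path <- function(f) file.path(output_dir, f)
    write_plot_table(table, path("plots.csv"))
    utils::write.csv(diagnostics, path("diagnostics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(vario$empirical), path("variogram.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(
      nugget = vario$model$nugget, sill = vario$model$sill,
      range = vario$model$range,
      nugget_ratio_percent = vario$class$nugget_ratio_percent,
      dependence = vario$class$label, transform = transform,
      lag_step = vario$lags$lag_step, n_lags = vario$lags$n_lags,
      max_dist = vario$lags$max_dist),
      path("variogram_model.csv"), row.names = FALSE)
    write_raster_ascii(surface, path("surface.asc"))
    utils::write.csv(cv$residuals, path("cv_residuals.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(mode = cv$mode, me = cv$me, rmse = cv$rmse,
                                n_train = cv$n_train, n_test = cv$n_test,
                                seed = cv$seed),
                     path("cv_summary.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(plot_id = hotspot$plot_id, g_star = hotspot$g_star,
                 z = hotspot$z, category = hotspot$category),
      path("hotspot.csv"), row.names = FALSE)
    if (!is.null(geodetector)) {
      utils::write.csv(geodetector$factors, path("geodetector_factors.csv"),
                       row.names = FALSE)
      utils::write.csv(geodetector$interactions,
                       path("geodetector_interactions.csv"), row.names = FALSE)
    }
    files <- setdiff(list.files(output_dir), "manifest.json")
    manifest <- list(
      package = "eskrig",
      version = as.character(utils::packageVersion("eskrig")),
      seed = config$seed,
      config = config,
      files = as.list(tools::md5sum(file.path(output_dir, files)))
    )
    names(manifest$files) <- files
    jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  }

  invisible(list(table = table, diagnostics = diagnostics,
                 composite = composite, variogram = vario, surface = surface,
                 cv = cv, hotspot = hotspot, geodetector = geodetector,
                 manifest = manifest, region = region))
}
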