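#' Read a plot table from CSV
#'
#' Plot tables are comma-separated UTF-8 text with a mandatory header and at
#' least the columns `plot_id`, `x`, `y`; every other column is a service or
#' driver. Validation enforces unique ids, finite numeric coordinates, and
#' finite nonnegative numeric service values, naming the offending row and
#' column on failure.
#'
#' @param path CSV file path.
#' @param service_cols Service column names; default: every column other than
#'   `plot_id`, `x`, `y` and `driver_cols`.
#' @param driver_cols Driver column names (exempt from the nonnegativity
#'   check).
#' @return The validated data.frame, with attributes `services` and
#'   `drivers`.
#' @export
read_plot_table <- function(path, service_cols = NULL,
                            driver_cols = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plot_id", "x", "y")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(table$plot_id)
  if (any(dup)) {
    stop(sprintf("duplicated plot_id `%s` at row %d", table$plot_id[dup][1],
                 which(dup)[1]), call. = FALSE)
  }
  for (col in c("x", "y")) {
    if (!is.numeric(table[[col]]) || !all(is.finite(table[[col]]))) {
      stop(sprintf("column `%s` must be finite numeric", col), call. = FALSE)
    }
  }
  if (is.null(service_cols)) {
    service_cols <- setdiff(names(table), c(required, driver_cols))
  }
  for (col in service_cols) {
    v <- table[[col]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      bad <- if (is.numeric(v)) which(!is.finite(v))[1] else 1L
      stop(sprintf("service column `%s` must be finite numeric (row %d)",
                   col, bad), call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("negative service value in column `%s`, row %d",
                   col, which(v < 0)[1]), call. = FALSE)
    }
  }
  attr(table, "services") <- service_cols
  attr(table, "drivers") <- driver_cols
  table
}

#' Write a plot table to CSV
#'
#' @param table Plot table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a raster surface as an ESRI ASCII grid
#'
#' Standard `.asc` layout: `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value` header, then one row of cell values per line,
#' north to south. Values are printed with full double precision so that a
#' read-back reproduces the grid.
#'
#' @param surface A [raster_surface()].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster_ascii <- function(surface, path) {
  stopifnot(inherits(surface, "raster_surface"))
  vals <- surface$values
  vals[is.na(vals)] <- surface$nodata
  header <- c(
    sprintf("ncols %d", surface$n_cols),
    sprintf("nrows %d", surface$n_rows),
    sprintf("xllcorner %.10g", surface$origin_x),
    sprintf("yllcorner %.10g", surface$origin_y),
    sprintf("cellsize %.10g", surface$cell_size_m),
    sprintf("NODATA_value %.10g", surface$nodata)
  )
  rows <- apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file path.
#' @param transform Scale tag to attach (`"raw"` or `"log"`).
#' @return A [raster_surface()]; nodata cells become `NA`.
#' @export
read_raster_ascii <- function(path, transform = "raw") {
  lines <- readLines(path)
  header <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(header), "\\s+"))
  vals <- as.numeric(kv[, 2])
  names(vals) <- tolower(kv[, 1])
  grid <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  grid[grid == vals[["nodata_value"]]] <- NA
  stopifnot(nrow(grid) == vals[["nrows"]], ncol(grid) == vals[["ncols"]])
  raster_surface(vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]],
                 grid, nodata = vals[["nodata_value"]], transform = transform)
}
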