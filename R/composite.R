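#' Moment-based distribution diagnostics
#'
#' Kriging presumes approximately normal data, so each service column is
#' screened by its sample skewness and kurtosis before and after log
#' transformation. Skewness is the standardized third central moment
#' `g1 = m3 / m2^(3/2)`; kurtosis uses the Pearson convention
#' `m4 / m2^2` (a normal distribution gives 3, not 0).
#'
#' @param values Numeric vector, `n >= 3`.
#' @param transform `"none"` or `"log"`; with `"log"` all values must be > 0.
#' @return A `distribution_diagnostics` list with `skewness`, `kurtosis`,
#'   `transform` and `n`.
#' @export
#' @examples
#' distribution_diagnostics(rlnorm(100), transform = "log")
distribution_diagnostics <- function(values, transform = c("none", "log")) {
  transform <- match.arg(transform)
  if (!is.numeric(values) || length(values) < 3 || anyNA(values)) {
    stop("`values` must be numeric without NAs, n >= 3", call. = FALSE)
  }
  if (transform == "log") {
    if (any(values <= 0)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    values <- log(values)
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) {
    stop("degenerate distribution: zero variance", call. = FALSE)
  }
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  structure(list(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2,
                 transform = transform, n = length(values)),
            class = "distribution_diagnostics")
}

#' Min-Max normalization onto \[0, 1\]
#'
#' Linear, order-preserving rescaling `(x - min) / (max - min)` mapping the
#' minimum to 0 and the maximum to 1, used to strip units from services
#' measured on incommensurable scales before they are combined.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @return Normalized vector with attributes `xmin` and `xmax` holding the
#'   bounds used.
#' @export
#' @examples
#' min_max_normalize(c(2, 4, 6))
min_max_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || anyNA(values)) {
    stop("`values` must be numeric without NAs, n >= 2", call. = FALSE)
  }
  xmin <- min(values)
  xmax <- max(values)
  if (xmax == xmin) {
    stop("degenerate range: max equals min, normalization undefined",
         call. = FALSE)
  }
  out <- (values - xmin) / (xmax - xmin)
  attr(out, "xmin") <- xmin
  attr(out, "xmax") <- xmax
  out
}

#' Equal-weight composite ecosystem-service score
#'
#' Each named service column is Min-Max normalized, the normalized columns
#' are combined as a weighted sum (equal weights by default, so no service
#' dominates by unit or magnitude), and the sum is Min-Max normalized again.
#' The composite therefore lies in `[0, 1]` and attains both endpoints.
#'
#' @param table Plot table data.frame.
#' @param service_names At least two service column names.
#' @param weights Optional positive weights, one per service; default equal.
#' @return A `composite_result` list: `normalized` (data.frame of normalized
#'   service columns), `composite` (numeric vector in `[0, 1]`), `bounds`
#'   (data.frame of the Min-Max bounds per service and for the pre-normalized
#'   sum).
#' @export
composite_es <- function(table, service_names, weights = NULL) {
  if (length(service_names) < 2) {
    stop("composite requires at least two services", call. = FALSE)
  }
  missing_cols <- setdiff(service_names, names(table))
  if (length(missing_cols) > 0) {
    stop("missing service column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- rep(1, length(service_names))
  }
  if (length(weights) != length(service_names) || any(weights <= 0)) {
    stop("`weights` must be positive, one per service", call. = FALSE)
  }

  normalized <- data.frame(row.names = seq_len(nrow(table)))
  bounds <- data.frame(column = character(0), xmin = numeric(0),
                       xmax = numeric(0))
  total <- numeric(nrow(table))
  for (i in seq_along(service_names)) {
    nm <- service_names[i]
    norm <- tryCatch(min_max_normalize(table[[nm]]), error = function(e) {
      stop(sprintf("service `%s`: %s", nm, conditionMessage(e)), call. = FALSE)
    })
    normalized[[nm]] <- as.numeric(norm)
    bounds <- rbind(bounds, data.frame(column = nm, xmin = attr(norm, "xmin"),
                                       xmax = attr(norm, "xmax")))
    total <- total + weights[i] * as.numeric(norm)
  }
  composite <- min_max_normalize(total)
  bounds <- rbind(bounds, data.frame(column = "composite_sum",
                                     xmin = attr(composite, "xmin"),
                                     xmax = attr(composite, "xmax")))
  structure(list(normalized = normalized, composite = as.numeric(composite),
                 bounds = bounds, service_names = service_names,
                 weights = weights),
            class = "composite_result")
}

#' @export
print.distribution_diagnostics <- function(x, ...) {
  cat(sprintf("distribution diagnostics (n = %d, transform = %s)\n",
              x$n, x$transform))
  cat(sprintf("  skewness: %.5f\n  kurtosis: %.5f (Pearson; normal = 3)\n",
              x$skewness, x$kurtosis))
  invisible(x)
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf("composite ES over %d services (%s)\n",
              length(x$service_names), paste(x$service_names, collapse = ", ")))
  cat(sprintf("  composite range: [%.3f, %.3f], mean %.3f\n",
              min(x$composite), max(x$composite), mean(x$composite)))
  invisible(x)
}
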