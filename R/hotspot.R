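#' Distance-band spatial weights
#'
#' Binary symmetric weights: `W_ij = 1` iff the Euclidean distance between
#' points i and j is at most `d`. With `include_self = TRUE` (the Gi*
#' convention) every point is its own neighbor.
#'
#' @param locations data.frame with columns `x`, `y` (>= 2 points).
#' @param d Distance band, metres, > 0.
#' @param include_self Include each point in its own neighborhood.
#' @return A `spatial_weights` list: binary matrix `W`, `d`, `include_self`.
#'   Points with no neighbor besides themselves trigger an isolated-point
#'   warning listing their indices.
#' @export
distance_band_weights <- function(locations, d, include_self = TRUE) {
  assert_locations(locations, min_n = 2L)
  assert_scalar_number(d, "d", positive = TRUE)
  dist <- pairwise_distances(locations)
  W <- (dist <= d) * 1
  diag(W) <- if (include_self) 1 else 0
  isolated <- which(rowSums(W) - diag(W) == 0)
  if (length(isolated) > 0) {
    warning("isolated point(s) with no neighbor within the band: ",
            paste(isolated, collapse = ", "), call. = FALSE)
  }
  structure(list(W = W, d = d, include_self = include_self,
                 n = nrow(locations)),
            class = "spatial_weights")
}

#' Getis-Ord Gi* hot/cold-spot statistic
#'
#' Per point, `Gi*(d) = sum_j W_ij X_j / sum_j X_j` compares the neighborhood
#' sum of values to the global sum; its z-score, computed from the standard
#' Getis-Ord randomization moments (the ArcGIS Gi* formulation), flags
#' significant clusters of high values (hot spots, z > 0) or low values
#' (cold spots, z < 0). The statistic assumes nonnegative X, so values with a
#' negative minimum (e.g. log-transformed services) are shifted to be
#' positive first; the shift is recorded and leaves the z-score unchanged.
#'
#' @param values Numeric values aligned with the weights (n >= 3, nonzero
#'   variance).
#' @param weights A [distance_band_weights()] result.
#' @return A `hotspot_result` data.frame with columns `index`, `g_star`,
#'   `expected`, `z`, `category` (see [classify_hot_cold()]); attributes
#'   `shift` and `d`.
#' @export
getis_ord_gi_star <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- weights$n
  if (length(values) != n) {
    stop("`values` must align with the weights", call. = FALSE)
  }
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("degenerate input: zero variance, no spatial signal definable",
         call. = FALSE)
  }
  shift <- 0
  if (min(values) <= 0) {
    shift <- -min(values) + stats::sd(values) * 1e-3
    values <- values + shift
  }
  W <- weights$W
  xbar <- mean(values)
  s <- sqrt(mean(values^2) - xbar^2)
  wi <- rowSums(W)                  # sum of weights incl. self for Gi*
  wx <- as.numeric(W %*% values)
  g_star <- wx / sum(values)
  expected <- wi / n
  # standard Gi* z-score: (sum_j w_ij x_j - xbar W_i) / (S sqrt((n S1i - W_i^2)/(n-1)))
  s1 <- rowSums(W^2)                # = W_i for binary weights
  denom_sq <- (n * s1 - wi^2) / (n - 1)
  clipped <- denom_sq < 0
  denom_sq[clipped] <- 0
  z <- ifelse(denom_sq > 0, (wx - xbar * wi) / (s * sqrt(denom_sq)), NA_real_)
  out <- data.frame(index = seq_len(n), g_star = g_star, expected = expected,
                    z = z, category = classify_hot_cold(z))
  structure(out, shift = shift, d = weights$d,
            variance_clipped = any(clipped),
            class = c("hotspot_result", "data.frame"))
}

#' Classify Gi* z-scores into hot/cold categories
#'
#' Two-sided normal thresholds: `|z| >= 2.58` at 99% confidence, `>= 1.96` at
#' 95%, `>= 1.65` at 90%; positive z marks hot spots (high-value clusters),
#' negative z cold spots.
#'
#' @param z Numeric z-scores (NA allowed).
#' @return Character vector over `hot99, hot95, hot90, not_significant,
#'   cold90, cold95, cold99`.
#' @export
#' @examples
#' classify_hot_cold(c(3, -2, 1))
classify_hot_cold <- function(z) {
  out <- rep(NA_character_, length(z))
  ok <- !is.na(z)
  out[ok] <- ifelse(z[ok] >= 2.58, "hot99",
             ifelse(z[ok] >= 1.96, "hot95",
             ifelse(z[ok] >= 1.65, "hot90",
             ifelse(z[ok] <= -2.58, "cold99",
             ifelse(z[ok] <= -1.96, "cold95",
             ifelse(z[ok] <= -1.65, "cold90", "not_significant"))))))
  out
}

#' Sweep Gi* over increasing distance thresholds
#'
#' Runs [getis_ord_gi_star()] at each band in `d_list`; as the threshold
#' grows, fragmented patches are progressively absorbed into larger
#' neighborhoods, so the count of significant points traces the scale of
#' clustering.
#'
#' @param values Numeric values.
#' @param locations data.frame with columns `x`, `y`.
#' @param d_list Strictly increasing distance bands, metres.
#' @param include_self Passed to [distance_band_weights()].
#' @return List with `summary` (data.frame `d`, `n_hot95`, `n_cold95`,
#'   `n_significant` at the 95% level) and `results` (one `hotspot_result`
#'   per band).
#' @export
distance_threshold_sweep <- function(values, locations, d_list,
                                     include_self = TRUE) {
  if (is.unsorted(d_list, strictly = TRUE)) {
    stop("`d_list` must be strictly increasing", call. = FALSE)
  }
  results <- lapply(d_list, function(d) {
    w <- suppressWarnings(distance_band_weights(locations, d, include_self))
    getis_ord_gi_star(values, w)
  })
  summary <- data.frame(
    d = d_list,
    n_hot95 = vapply(results, function(r) sum(r$z >= 1.96, na.rm = TRUE),
                     numeric(1)),
    n_cold95 = vapply(results, function(r) sum(r$z <= -1.96, na.rm = TRUE),
                      numeric(1))
  )
  summary$n_significant <- summary$n_hot95 + summary$n_cold95
  list(summary = summary, results = results)
}

#' @export
print.hotspot_result <- function(x, ...) {
  tab <- table(factor(x$category,
                      levels = c("cold99", "cold95", "cold90",
                                 "not_significant", "hot90", "hot95", "hot99")))
  cat(sprintf("Gi* hotspot analysis (d = %.0f m, n = %d)\n",
              attr(x, "d"), nrow(x)))
  print(tab)
  invisible(x)
}
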