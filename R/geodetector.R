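#' Jenks natural-breaks discretization
#'
#' Optimal 1-D partition of a continuous variable into `k` classes minimizing
#' the within-class sum of squared deviations (Fisher's exact dynamic
#' programme, the method behind ArcGIS "natural breaks"). Deterministic; on
#' ties the lower break is taken. Labels are ordered by value: class 1 holds
#' the smallest values.
#'
#' @param values Numeric vector, `n >= k`, non-constant.
#' @param k Number of classes (>= 2). If there are fewer distinct values than
#'   `k`, `k` is reduced with a warning.
#' @param source Optional label recording the variable the strata came from.
#' @return A `stratified_variable` list: `labels` (integer in `1..k`),
#'   `breaks` (upper class bounds, length `k`), `k`, `source`, `wcss`
#'   (achieved within-class sum of squares).
#' @export
#' @examples
#' jenks_breaks(c(1, 1.1, 10, 10.1, 100, 100.1), k = 3)$labels
jenks_breaks <- function(values, k, source = NULL) {
  if (!is.numeric(values) || anyNA(values)) {
    stop("`values` must be numeric without NAs", call. = FALSE)
  }
  distinct <- sort(unique(values))
  if (length(distinct) < 2) {
    stop("`values` must not be constant", call. = FALSE)
  }
  if (k < 2 || k != round(k)) stop("`k` must be an integer >= 2", call. = FALSE)
  if (length(values) < k) {
    stop(sprintf("need n >= k (n = %d, k = %d)", length(values), k),
         call. = FALSE)
  }
  if (length(distinct) < k) {
    warning(sprintf("only %d distinct values; reducing k from %d",
                    length(distinct), k), call. = FALSE)
    k <- length(distinct)
  }

  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # within-class SSD of sorted x[i..j]
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[l, j]: minimal WCSS splitting x[1..j] into l classes; B records argmin
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- vapply(seq_len(n), function(j) ssd(1, j), numeric(1))
  for (l in 2:k) {
    for (j in l:n) {
      # last class starts at i; pick smallest i on ties (lower break)
      starts <- l:j
      costs <- D[l - 1, starts - 1] +
        vapply(starts, function(i) ssd(i, j), numeric(1))
      pick <- which.min(costs)
      D[l, j] <- costs[pick]
      B[l, j] <- starts[pick]
    }
  }
  # backtrack class boundaries (positions in the sorted vector)
  ends <- integer(k)
  ends[k] <- n
  for (l in k:2) {
    ends[l - 1] <- B[l, ends[l]] - 1L
  }
  breaks <- x[ends]                           # upper value bound per class
  labels <- vapply(values, function(v) {
    as.integer(which(v <= breaks)[1])
  }, integer(1))
  structure(list(labels = labels, breaks = breaks, k = k,
                 source = source, wcss = D[k, n]),
            class = "stratified_variable")
}

strata_labels <- function(strata) {
  if (inherits(strata, "stratified_variable")) strata$labels else strata
}

#' Geographical-detector factor q-statistic
#'
#' `q = 1 - sum_m N_m sigma_m^2 / (N sigma^2)` with population (divide-by-N)
#' variances, so the within/total decomposition is exact and `q` lies in
#' `[0, 1]`: 0 when the stratification explains none of the variable's
#' variance, 1 when the variable is constant within every stratum. The
#' p-value is the noncentral-F significance test of the geographical
#' detector: `F = ((N - L) / (L - 1)) * q / (1 - q)` against
#' `F(L - 1, N - L; lambda)` with noncentrality
#' `lambda = (sum_m N_m ybar_m^2 - (sum_m sqrt(N_m) ybar_m)^2 / N) / sigma^2`.
#'
#' @param y_values Numeric response aligned with the strata.
#' @param strata A [jenks_breaks()] result or an integer/factor label vector.
#' @return A `factor_result` list: `q`, `p`, `n`, `n_strata`, `variance`
#'   (population), `strata_summary` (data.frame `stratum`, `n`, `mean`,
#'   `variance`).
#' @export
#' @examples
#' factor_q(1:6, rep(c("A", "B"), each = 3))
factor_q <- function(y_values, strata) {
  g <- strata_labels(strata)
  if (length(g) != length(y_values)) {
    stop("`strata` must align with `y_values`", call. = FALSE)
  }
  g <- factor(g)
  empty <- levels(g)[tabulate(g) == 0]
  if (length(empty) > 0) {
    warning("dropping empty stratum(-a): ", paste(empty, collapse = ", "),
            call. = FALSE)
    g <- droplevels(g)
  }
  N <- length(y_values)
  L <- nlevels(g)
  if (L < 1) stop("no strata", call. = FALSE)
  if (N < L + 1) stop("need N >= L + 1", call. = FALSE)
  popvar <- function(u) mean((u - mean(u))^2)
  sigma2 <- popvar(y_values)
  if (sigma2 == 0) {
    stop("degenerate input: zero total variance", call. = FALSE)
  }
  nm <- as.numeric(table(g))
  means <- as.numeric(tapply(y_values, g, mean))
  vars <- as.numeric(tapply(y_values, g, popvar))
  q <- 1 - sum(nm * vars) / (N * sigma2)

  p <- if (L < 2) {
    1
  } else if (q >= 1 - 1e-14) {
    0
  } else {
    f_stat <- ((N - L) / (L - 1)) * q / (1 - q)
    lambda <- (sum(nm * means^2) - sum(sqrt(nm) * means)^2 / N) / sigma2
    stats::pf(f_stat, L - 1, N - L, ncp = lambda, lower.tail = FALSE)
  }
  structure(list(q = q, p = p, n = N, n_strata = L, variance = sigma2,
                 strata_summary = data.frame(stratum = levels(g), n = nm,
                                             mean = means, variance = vars)),
            class = "factor_result")
}

#' Classify a two-factor interaction
#'
#' Compares the q of the A-and-B cross-classification with the individual q's
#' using the standard geographical-detector rule table, where the joint
#' reference for enhancement beyond both factors is the sum `q(A) + q(B)`:
#' below both minima the interaction weakens nonlinearly, between the minima
#' and maxima it weakens single factors, above the maximum but below the sum
#' it is two-factor enhancement, equal to the sum (within `tol`) the factors
#' are independent, and above the sum the enhancement is nonlinear.
#'
#' @param q_a,q_b,q_ab Individual and cross-classification q values.
#' @param tol Tolerance for the independence equality.
#' @return One of `"nonlinear_weakening"`,
#'   `"single_factor_nonlinear_weakening"`, `"two_factor_enhancement"`,
#'   `"independence"`, `"nonlinear_enhancement"`.
#' @export
#' @examples
#' classify_interaction(0.3, 0.4, 0.9)
classify_interaction <- function(q_a, q_b, q_ab, tol = 1e-9) {
  lo <- min(q_a, q_b)
  hi <- max(q_a, q_b)
  if (q_ab < lo) {
    "nonlinear_weakening"
  } else if (q_ab <= hi) {
    "single_factor_nonlinear_weakening"
  } else if (abs(q_ab - (q_a + q_b)) <= tol) {
    "independence"
  } else if (q_ab < q_a + q_b) {
    "two_factor_enhancement"
  } else {
    "nonlinear_enhancement"
  }
}

#' Geographical-detector interaction detector
#'
#' Computes the factor q of each stratification and of their
#' cross-classification (pairwise label product), then classifies the joint
#' influence with [classify_interaction()].
#'
#' @param y_values Numeric response.
#' @param strata_a,strata_b Stratifications ([jenks_breaks()] results or
#'   label vectors) aligned with `y_values`.
#' @return An `interaction_result` list: `q_a`, `q_b`, `q_ab`,
#'   `classification`.
#' @export
interaction_q <- function(y_values, strata_a, strata_b) {
  a <- strata_labels(strata_a)
  b <- strata_labels(strata_b)
  cross <- interaction(factor(a), factor(b), drop = TRUE)
  if (nlevels(cross) < 2) {
    stop("cross-classification must have >= 2 nonempty strata", call. = FALSE)
  }
  q_a <- factor_q(y_values, a)$q
  q_b <- factor_q(y_values, b)$q
  q_ab <- factor_q(y_values, cross)$q
  structure(list(q_a = q_a, q_b = q_b, q_ab = q_ab,
                 classification = classify_interaction(q_a, q_b, q_ab)),
            class = "interaction_result")
}

#' Run the full geographical-detector analysis of a plot table
#'
#' Discretizes each continuous driver by Jenks natural breaks into `k`
#' classes (drivers that are already categorical -- factors, characters, or
#' integer-valued columns with at most `k` distinct values -- are used as
#' given), computes every factor q with its significance, and every pairwise
#' interaction. Factors are ranked by q, descending.
#'
#' @param table Plot table data.frame.
#' @param y_service Response column name.
#' @param driver_names Driver column names.
#' @param k Number of natural-breaks classes for continuous drivers.
#' @param p_threshold Significance threshold for flagging factors.
#' @return A `geodetector_result` list: `factors` (data.frame `driver`, `q`,
#'   `p`, `significant`, ranked by q descending), `interactions` (data.frame
#'   `driver_a`, `driver_b`, `q_a`, `q_b`, `q_ab`, `classification`),
#'   `strata` (named list of label vectors), `k`.
#' @export
run_geodetector <- function(table, y_service, driver_names, k = 5,
                            p_threshold = 0.1) {
  missing_cols <- setdiff(c(y_service, driver_names), names(table))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- table[[y_service]]
  strata <- lapply(driver_names, function(nm) {
    col <- table[[nm]]
    already_categorical <- is.factor(col) || is.character(col) ||
      (is.numeric(col) && all(col == round(col)) &&
         length(unique(col)) <= k)
    if (already_categorical) {
      as.integer(factor(col))
    } else {
      jenks_breaks(col, k, source = nm)$labels
    }
  })
  names(strata) <- driver_names

  factors <- do.call(rbind, lapply(driver_names, function(nm) {
    fr <- factor_q(y, strata[[nm]])
    data.frame(driver = nm, q = fr$q, p = fr$p,
               significant = fr$p < p_threshold)
  }))
  factors <- factors[order(-factors$q), ]
  rownames(factors) <- NULL

  pairs <- if (length(driver_names) >= 2) {
    utils::combn(driver_names, 2, simplify = FALSE)
  } else {
    list()
  }
  interactions <- do.call(rbind, lapply(pairs, function(p2) {
    ir <- interaction_q(y, strata[[p2[1]]], strata[[p2[2]]])
    data.frame(driver_a = p2[1], driver_b = p2[2], q_a = ir$q_a, q_b = ir$q_b,
               q_ab = ir$q_ab, classification = ir$classification)
  }))
  structure(list(factors = factors, interactions = interactions,
                 strata = strata, k = k, y_service = y_service,
                 p_threshold = p_threshold),
            class = "geodetector_result")
}

#' @export
print.factor_result <- function(x, ...) {
  cat(sprintf("factor detector: q = %.5f, p = %.4g (N = %d, %d strata)\n",
              x$q, x$p, x$n, x$n_strata))
  invisible(x)
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction detector: q(A) = %.4f, q(B) = %.4f, q(A∩B) = %.4f -> %s\n",
              x$q_a, x$q_b, x$q_ab, x$classification))
  invisible(x)
}

#' @export
print.geodetector_result <- function(x, ...) {
  cat(sprintf("geodetector on `%s` (%d drivers, k = %d)\n",
              x$y_service, nrow(x$factors), x$k))
  print(x$factors, row.names = FALSE)
  if (!is.null(x$interactions) && nrow(x$interactions) > 0) {
    cat("interactions:\n")
    print(x$interactions, row.names = FALSE)
  }
  invisible(x)
}
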