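#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`, then
#' restores the previous RNG state, so that seeded operations are pure
#' functions of their arguments and do not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# shared argument checks ------------------------------------------------------

assert_locations <- function(locations, min_n = 1L) {
  if (!is.data.frame(locations) || !all(c("x", "y") %in% names(locations))) {
    stop("`locations` must be a data.frame with numeric columns `x` and `y`",
         call. = FALSE)
  }
  if (!is.numeric(locations$x) || !is.numeric(locations$y) ||
      !all(is.finite(locations$x)) || !all(is.finite(locations$y))) {
    stop("location coordinates must be finite numerics", call. = FALSE)
  }
  if (nrow(locations) < min_n) {
    stop(sprintf("need at least %d locations, got %d", min_n, nrow(locations)),
         call. = FALSE)
  }
  invisible(locations)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Euclidean distance matrix between two coordinate sets (or one and itself)
pairwise_distances <- function(a, b = a) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  sqrt(dx * dx + dy * dy)
}
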