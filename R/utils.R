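#' @useDynLib magicqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor pchisq pf quantile rbinom rnorm rpois runif
#'   sd var setNames chisq.test qchisq ecdf median
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed the random number generator if a seed is given
#'
#' Sets the global RNG state when `seed` is non-NULL; a no-op otherwise.
#' All stochastic functions in the package route through this helper so a
#' single integer seed makes a whole analysis reproducible.
#' @param seed integer or NULL
#' @keywords internal
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# greatest index i with x[i] <= v, clamped to [1, n]; x sorted ascending
.interval_index <- function(v, x) {
  pmin(pmax(findInterval(v, x), 1L), length(x))
}

# fast piecewise-linear interpolation on sorted anchors (both axes
# non-decreasing); clamps outside the anchor range
.interp <- function(x, xs, ys) {
  n <- length(xs)
  i <- pmin(pmax(findInterval(x, xs), 1L), n - 1L)
  dx <- xs[i + 1L] - xs[i]
  w <- ifelse(dx > 0, (x - xs[i]) / dx, 0)
  w <- pmin(pmax(w, 0), 1)
  ys[i] + w * (ys[i + 1L] - ys[i])
}
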