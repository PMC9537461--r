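#' Specific clearance of a unit operation
#'
#' The specific clearance SC = load / pool is the ratio of the specific
#' impurity concentration (amount per mg product) entering a unit operation
#' to that leaving it. SC > 1 means the step removes the impurity. Because
#' concentrations are normalized to product amount, SC is independent of
#' scale and volume.
#'
#' @param load,pool Positive specific concentrations in the load and pool.
#'   Vectorized; recycled to common length.
#' @return `load / pool`.
#' @seealso [compute_yield()] — its exact reciprocal.
#' @export
#' @examples
#' compute_specific_clearance(10, 1) # 10-fold clearance
compute_specific_clearance <- function(load, pool) {
  check_positive(load, "load")
  check_positive(pool, "pool")
  load / pool
}

#' Yield of a unit operation
#'
#' Y = pool / load for product amount or purity attributes (percent of the
#' desired isoform). The algebraic identity `yield * specific_clearance = 1`
#' holds for any positive pair.
#'
#' @inheritParams compute_specific_clearance
#' @return `pool / load`.
#' @export
compute_yield <- function(load, pool) {
  check_positive(load, "load")
  check_positive(pool, "pool")
  pool / load
}

check_positive <- function(x, what) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop(what, " must be positive and finite; offending value(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Scale a factor value to the \[-1, 1\] coded range
#'
#' Affine coding of a native-unit factor value against its design range:
#' the low end maps to -1, the high end to +1, the midpoint to 0. Values
#' outside the design range map outside \[-1, 1\]; extrapolation is flagged
#' by the callers, never silently clipped here.
#'
#' @param value Numeric vector in native units.
#' @param design_range `c(low, high)`, `low < high`.
#' @return Coded values `(value - mid) / half_range`.
#' @export
#' @examples
#' scale_factor(c(2, 5, 8), c(2, 8)) # -1, 0, 1
scale_factor <- function(value, design_range) {
  stopifnot(length(design_range) == 2L)
  lo <- design_range[1]; hi <- design_range[2]
  if (!(is.finite(lo) && is.finite(hi)) || lo >= hi) {
    stop("degenerate design_range: [", lo, ", ", hi, "]")
  }
  (value - (lo + hi) / 2) / ((hi - lo) / 2)
}

#' Invert the \[-1, 1\] coding back to native units
#'
#' @param coded Coded values.
#' @inheritParams scale_factor
#' @return Native-unit values; exact inverse of [scale_factor()].
#' @export
unscale_factor <- function(coded, design_range) {
  stopifnot(length(design_range) == 2L)
  lo <- design_range[1]; hi <- design_range[2]
  if (!(is.finite(lo) && is.finite(hi)) || lo >= hi) {
    stop("degenerate design_range: [", lo, ", ", hi, "]")
  }
  coded * (hi - lo) / 2 + (lo + hi) / 2
}
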