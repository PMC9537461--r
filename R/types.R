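#' Define a critical quality attribute (CQA)
#'
#' A CQA is a measurable product property that must meet limits at drug
#' substance (DS). Impurities (e.g. host-cell protein, aggregates) must be
#' cleared downward and carry an upper specification limit; purities
#' (e.g. monomer content) must be kept up and carry a lower limit.
#'
#' @param name Attribute name, e.g. `"HCP"`.
#' @param direction `"impurity"` or `"purity"`.
#' @param unit Unit of the specific concentration, e.g. `"ng/mg"` or `"%"`.
#'   Percent-type CQAs (`"%"` or `"percent"`) are physically capped at 100
#'   during simulation and their specification values must lie in \[0, 100\].
#' @param ds_spec Drug-substance specification limit (a single number). Its
#'   side follows the direction: upper for impurities, lower for purities.
#' @param ds_spec_second Optional second (opposite-side) limit; `NA` for the
#'   one-sided specifications typical of purification CQAs.
#' @param fit_scale Scale on which the DS distribution is fitted for OOS
#'   estimation: `"raw"` (default) or `"log"` for attributes spanning decades.
#'
#' @return An object of class `"quality_attribute"`.
#' @export
#' @examples
#' quality_attribute("HCP", "impurity", "ng/mg", ds_spec = 10)
quality_attribute <- function(name, direction = c("impurity", "purity"),
                              unit = "ng/mg", ds_spec,
                              ds_spec_second = NA_real_,
                              fit_scale = c("raw", "log")) {
  direction <- match.arg(direction)
  fit_scale <- match.arg(fit_scale)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(ds_spec)) stop("ds_spec must be finite for CQA '", name, "'")
  percent <- unit %in% c("%", "percent")
  if (percent && (ds_spec < 0 || ds_spec > 100)) {
    stop("percent-type CQA '", name, "' needs ds_spec in [0, 100], got ", ds_spec)
  }
  side <- if (direction == "impurity") "upper" else "lower"
  spec <- list(lower = NA_real_, upper = NA_real_)
  spec[[side]] <- ds_spec
  if (is.finite(ds_spec_second)) {
    other <- setdiff(c("lower", "upper"), side)
    spec[[other]] <- ds_spec_second
    if (!is.na(spec$lower) && !is.na(spec$upper) && spec$lower >= spec$upper) {
      stop("lower specification limit must be below the upper limit")
    }
  }
  structure(list(name = name, direction = direction, unit = unit,
                 percent = percent, spec = spec, side = side,
                 fit_scale = fit_scale),
            class = "quality_attribute")
}

#' @export
print.quality_attribute <- function(x, ...) {
  lim <- c(if (!is.na(x$spec$lower)) paste(">=", x$spec$lower),
           if (!is.na(x$spec$upper)) paste("<=", x$spec$upper))
  cat(sprintf("<quality_attribute> %s (%s, %s), DS spec %s\n",
              x$name, x$direction, x$unit, paste(lim, collapse = ", ")))
  invisible(x)
}

#' Define a process parameter with its normal operating range (NOR)
#'
#' The NOR is the distribution of a controlled process parameter around its
#' set-point that captures common, uncontrollable operational variability.
#' It is modelled as Normal(set-point, cv * |set-point|) by default; uniform
#' and truncated-normal variants are available for parameters that are only
#' required to stay within a range.
#'
#' @param name Parameter name, e.g. `"elution_pH"`.
#' @param set_point Target operating value in native units (non-zero when a
#'   cv-based sd is used).
#' @param cv Coefficient of variation as a fraction (default 0.03, the
#'   conventional assumption when only set-points are available).
#' @param distribution `"normal"` (default), `"uniform"` (variance-matched to
#'   the normal NOR) or `"truncated_normal"` (truncated at +/- 3 sd).
#' @param design_range Length-2 numeric `c(low, high)` in native units; the
#'   range used for \[-1, 1\] factor scaling. Required for any parameter
#'   appearing in a DoE model.
#'
#' @return An object of class `"process_parameter"`.
#' @export
process_parameter <- function(name, set_point, cv = 0.03,
                              distribution = c("normal", "uniform",
                                               "truncated_normal"),
                              design_range = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(set_point)) stop("set_point must be finite")
  if (!is.finite(cv) || cv <= 0) stop("cv must be > 0 for '", name, "'")
  if (!is.null(design_range)) {
    stopifnot(length(design_range) == 2L)
    if (!(design_range[1] < design_range[2])) {
      stop("degenerate design_range for '", name, "'")
    }
    if (set_point < design_range[1] || set_point > design_range[2]) {
      stop("set_point of '", name, "' lies outside its design_range")
    }
  }
  structure(list(name = name, set_point = set_point, cv = cv,
                 distribution = distribution, design_range = design_range),
            class = "process_parameter")
}

#' @export
print.process_parameter <- function(x, ...) {
  cat(sprintf("<process_parameter> %s: set-point %g, cv %g (%s)\n",
              x$name, x$set_point, x$cv, x$distribution))
  invisible(x)
}

# The limit relevant for a one-sided risk assessment of this CQA:
# upper for impurities, lower for purities.
primary_limit <- function(cqa) cqa$spec[[cqa$side]]
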