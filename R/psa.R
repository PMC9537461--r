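# Parameter sensitivity analysis: sweep imposed pool values at a unit
# operation, estimate the downstream OOS probability at drug substance, and
# invert the (monotone) curve at the pre-defined threshold to obtain the
# intermediate acceptance criterion.

.cqa_fit_scale <- function(cqa, config) cqa$fit_scale %||% config$fit_scale

#' Build the screening grid of imposed pool values
#'
#' The screening range is mean +/- `width_sd` standard deviations of the
#' observed manufacturing pool values at the unit operation, divided into
#' `n_points` equidistant evaluation points (endpoints included). The lower
#' bound is clipped to a small positive epsilon (concentrations are
#' positive) and, for percent-type CQAs, the upper bound to 100; the grid is
#' re-spaced after clipping. The grid runs toward the risky side: increasing
#' pool values for impurities, decreasing for purities.
#'
#' @param pool_values Manufacturing pool values at the unit operation (>= 2).
#' @param cqa The [quality_attribute()].
#' @param n_points Number of grid points (default 15).
#' @param width_sd Half-width in standard deviations (default 10).
#' @param eps Positive lower clip; defaults to `mean/1000`.
#' @return An object of class `"screening_grid"` with `values` ordered
#'   toward the risky side and a `provenance` record.
#' @export
screening_grid <- function(pool_values, cqa, n_points = 15L, width_sd = 10,
                           eps = NULL) {
  pool_values <- pool_values[is.finite(pool_values)]
  if (length(pool_values) < 2L) stop("screening_grid needs >= 2 pool values")
  m <- mean(pool_values); s <- stats::sd(pool_values)
  if (s == 0) {
    stop("zero standard deviation in pool values (all identical, e.g. all at ",
         "the limit of quantification): integrated process modelling cannot ",
         "be applied here — flag the unit operation iac_equals_ds_spec")
  }
  if (is.null(eps)) eps <- m / 1000
  lo <- m - width_sd * s
  hi <- m + width_sd * s
  clipped <- FALSE
  if (lo < eps) { lo <- eps; clipped <- TRUE }
  if (cqa$percent && hi > 100) { hi <- 100; clipped <- TRUE }
  if (!(lo < hi)) stop("degenerate screening range after clipping")
  values <- seq(lo, hi, length.out = n_points)
  if (cqa$direction == "purity") values <- rev(values)
  structure(list(values = values, cqa = cqa$name,
                 provenance = list(mean = m, sd = s, width_sd = width_sd,
                                   n_points = n_points, clipped = clipped)),
            class = "screening_grid")
}

#' Estimate the OOS-versus-pool-value curve at one unit operation
#'
#' For each grid value the CQA's pool at the unit operation is set to that
#' fixed value, the downstream chain is simulated with `config$n_runs`
#' Monte-Carlo runs (process parameters sampled from their normal operating
#' ranges), and the OOS probability of the resulting drug-substance
#' distribution is computed. All grid points share common random numbers (a
#' seed sub-stream derived from the master seed and the UO/CQA pair), which
#' smooths the curve for the threshold inversion.
#'
#' @param chain A [process_chain()].
#' @param uo_id Unit operation (inside the CQA's modelled sub-range).
#' @param cqa CQA name.
#' @param grid A [screening_grid()]; built from manufacturing data when
#'   omitted arguments are supplied via [derive_all_iacs()].
#' @param config A [sim_config()].
#' @return An object of class `"psa_result"` (without the acceptance
#'   criterion; see [derive_iac()]).
#' @export
psa_curve <- function(chain, uo_id, cqa, grid, config = sim_config()) {
  stopifnot(inherits(grid, "screening_grid"), cqa %in% names(chain$cqas))
  cq <- chain$cqas[[cqa]]
  r <- chain$ranges[[cqa]]
  if (uo_id < r[1] || uo_id > r[2]) {
    stop("UO ", uo_id, " outside the modelled sub-range of '", cqa, "'")
  }
  fit_scale <- .cqa_fit_scale(cq, config)
  point_seed <- derive_seed(config$seed, uo_id, match(cqa, names(chain$cqas)))
  oos <- vapply(grid$values, function(v) {
    cfg <- config
    cfg$seed <- point_seed   # common random numbers across grid points
    cfg$fixed_pool_overrides <- stats::setNames(list(v),
                                                paste0(uo_id, ":", cqa))
    sim <- ipm_simulate(chain, cfg, cqa = cqa)
    oos_probability(sim$ds[[cqa]], cq, fit_scale = fit_scale)$oos_probability
  }, numeric(1))
  structure(list(grid = grid, oos = oos, uo_id = as.integer(uo_id),
                 cqa = cqa, side = cq$side, n_runs = config$n_runs,
                 seed = config$seed, threshold = NA_real_,
                 iac = NA_real_, smoothed_oos = NULL),
            class = "psa_result")
}

#' Derive the intermediate acceptance criterion from a PSA curve
#'
#' Fits a monotone (isotonic, non-decreasing toward the risky side) curve to
#' the raw OOS estimates and interpolates the pool value at which it crosses
#' the OOS threshold, linearly between the bracketing grid points on the
#' probit (qnorm) scale of the OOS estimates. The criterion is an upper limit for
#' impurities and a lower limit for purities. If the curve never reaches the
#' threshold within the grid the result is `not_derivable` — the grid can be
#' widened, but no extrapolation is ever performed.
#'
#' @param psa A `"psa_result"` from [psa_curve()].
#' @param threshold OOS-probability threshold (default 0.05).
#' @return The `psa_result` with `smoothed_oos`, `threshold` and `iac`
#'   filled in; `iac` is `NA` with `status = "not_derivable"` when the curve
#'   does not bracket the threshold.
#' @export
derive_iac <- function(psa, threshold = 0.05) {
  stopifnot(inherits(psa, "psa_result"), threshold > 0, threshold < 1)
  x <- psa$grid$values
  yf <- stats::isoreg(seq_along(x), psa$oos)$yf
  psa$smoothed_oos <- yf
  psa$threshold <- threshold
  idx <- which(yf >= threshold)
  if (!length(idx) || idx[1] == 1L) {
    # never reaches the threshold inside the grid, or already beyond it at
    # the first (least risky) point: no bracketing, no extrapolation
    psa$iac <- NA_real_
    psa$status <- "not_derivable"
    return(psa)
  }
  i <- idx[1]
  # Interpolate the crossing between the bracketing grid points on the
  # probit scale: OOS curves are normal-tail-shaped, so qnorm(OOS) is close
  # to linear in the pool value while OOS itself is strongly convex —
  # raw-scale interpolation over a +/- 10 SD grid would bias the criterion
  # by several percent. Falls back to raw-scale interpolation when a
  # bracketing OOS estimate is exactly 0 or 1.
  y0 <- yf[i - 1]; y1 <- yf[i]
  t <- if (y0 > 0 && y1 < 1) {
    (stats::qnorm(threshold) - stats::qnorm(y0)) /
      (stats::qnorm(y1) - stats::qnorm(y0))
  } else {
    (threshold - y0) / (y1 - y0)
  }
  psa$iac <- x[i - 1] + t * (x[i] - x[i - 1])
  psa$status <- "ok"
  psa
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s at UO %d, %d grid points x %d runs\n",
              x$cqa, x$uo_id, length(x$grid$values), x$n_runs))
  if (!is.na(x$threshold)) {
    cat(sprintf("  iAC (%s limit, OOS threshold %g): %s\n", x$side,
                x$threshold,
                if (is.na(x$iac)) "not derivable within grid"
                else format(x$iac, digits = 6)))
  }
  invisible(x)
}

#' Derive the full intermediate-acceptance-criteria table
#'
#' Runs the parameter sensitivity analysis for every CQA at every unit
#' operation of its modelled sub-range and assembles the iAC table. The last
#' modelled unit operation's criterion is the drug-substance specification
#' limit itself; unit operations flagged `iac_equals_ds_spec` (no usable
#' data) also receive the DS limit, relying on the assumption that the
#' impurity does not increase there. Conventional mean +/- 3 sd baseline
#' limits from the manufacturing pool values are included for comparison.
#'
#' @param chain A [process_chain()].
#' @param mfg_data Manufacturing dataset (columns `uo_id`, `cqa`,
#'   `pool_value`, optionally `pool_loq`), used for the screening grids and
#'   the 3SD baseline.
#' @param config A [sim_config()].
#' @param threshold OOS threshold (default 0.05).
#' @return A data frame with one row per (CQA, UO): `uo_id`, `cqa`, `side`,
#'   `iac`, `method` (`"psa"`, `"ds_spec"` or `"ds_spec_fallback"`),
#'   `status`, `threshold`, `n_runs`, `seed`, `sd3_lower`, `sd3_upper`.
#' @export
derive_all_iacs <- function(chain, mfg_data, config = sim_config(),
                            threshold = config$oos_threshold) {
  validate_chain(chain)
  rows <- list()
  for (cq_name in names(chain$cqas)) {
    cq <- chain$cqas[[cq_name]]
    r <- chain$ranges[[cq_name]]
    flagged <- vapply(chain$uos, function(u) cq_name %in% u$fallback,
                      logical(1))
    uo_rows <- sort(unique(c(r[1]:r[2],
                             vapply(chain$uos[flagged], `[[`, integer(1), "id"))))
    for (k in uo_rows) {
      sel <- mfg_data$uo_id == k & mfg_data$cqa == cq_name
      pools <- mfg_data$pool_value[sel]
      all_loq <- "pool_loq" %in% names(mfg_data) &&
        any(sel) && all(mfg_data$pool_loq[sel])
      sd3 <- if (sum(is.finite(pools)) >= 2L && !all_loq) {
        three_sd_limits(pools)
      } else c(lower = NA_real_, upper = NA_real_)

      uo <- chain$uos[[as.character(k)]]
      is_flagged <- cq_name %in% uo$fallback
      if (is_flagged) {
        iac <- primary_limit(cq); method <- "ds_spec_fallback"; status <- "ok"
      } else if (k == r[2]) {
        iac <- primary_limit(cq); method <- "ds_spec"; status <- "ok"
      } else {
        res <- tryCatch({
          grid <- screening_grid(pools, cq)
          derive_iac(psa_curve(chain, k, cq_name, grid, config), threshold)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          iac <- primary_limit(cq); method <- "ds_spec_fallback"
          status <- conditionMessage(res)
        } else {
          iac <- res$iac; method <- "psa"; status <- res$status
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        uo_id = k, cqa = cq_name, side = cq$side, iac = iac,
        method = method, status = status, threshold = threshold,
        n_runs = config$n_runs, seed = config$seed,
        sd3_lower = unname(sd3["lower"]), sd3_upper = unname(sd3["upper"]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$cqa, out$uo_id), , drop = FALSE]
}

#' Compare PSA-derived criteria with the 3SD baseline
#'
#' For each PSA-derived criterion, reports whether the conventional +/- 3 sd
#' limit is tighter (i.e. raises alerts at pool values the integrated model
#' still considers acceptable): for impurities the relevant baseline is the
#' upper 3SD limit and "tighter" means `sd3_upper < iac`; for purities the
#' lower limit and `sd3_lower > iac`.
#'
#' @param iac_table Output of [derive_all_iacs()].
#' @return The table with logical column `sd3_tighter` (NA where either
#'   quantity is unavailable).
#' @export
compare_3sd <- function(iac_table) {
  base <- ifelse(iac_table$side == "upper", iac_table$sd3_upper,
                 iac_table$sd3_lower)
  tighter <- ifelse(iac_table$side == "upper", base < iac_table$iac,
                    base > iac_table$iac)
  tighter[iac_table$method != "psa"] <- NA
  iac_table$sd3_tighter <- tighter
  iac_table
}
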