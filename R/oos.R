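# Out-of-specification probability estimation and the 3SD baseline.

#' Upper confidence bound of a standard deviation
#'
#' One-sided upper chi-square confidence bound
#' `s * sqrt((n - 1) / qchisq(1 - level, n - 1))`. Used to inflate the
#' standard deviation of the fitted drug-substance distribution so that OOS
#' probabilities computed from few manufacturing runs are comparable with
#' those from hundreds of simulated runs. Decreases monotonically toward `s`
#' as `n` grows.
#'
#' @param s Sample standard deviation (> 0).
#' @param n Sample size (>= 2).
#' @param level Confidence level (default 0.80).
#' @param sided `"one"` (default, conservative one-sided bound) or `"two"`
#'   (upper end of the two-sided `level` interval).
#' @return The upper bound (>= `s` for `level >= 0.5`).
#' @export
#' @examples
#' upper_sd_ci(1, 10) # about 1.293
upper_sd_ci <- function(s, n, level = 0.80, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n < 2) stop("upper_sd_ci needs n >= 2, got ", n)
  stopifnot(s > 0, level > 0, level < 1)
  q <- if (sided == "one") 1 - level else (1 - level) / 2
  s * sqrt((n - 1) / stats::qchisq(q, df = n - 1))
}

.as_spec <- function(spec) {
  if (inherits(spec, "quality_attribute")) return(spec$spec)
  if (is.list(spec) && all(c("lower", "upper") %in% names(spec))) return(spec)
  if (is.numeric(spec) && !is.null(names(spec))) {
    return(list(lower = unname(spec["lower"]) %||% NA_real_,
                upper = unname(spec["upper"]) %||% NA_real_))
  }
  stop("spec must be a quality_attribute or list(lower=, upper=)")
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

#' Out-of-specification probability of a sample
#'
#' Fits a normal distribution with the arithmetic mean and the upper 80%
#' chi-square confidence bound of the standard deviation, then reports the
#' tail area beyond the drug-substance specification limit(s): upper tail
#' above an upper limit, lower tail below a lower limit, their sum for
#' two-sided specifications. For attributes spanning decades the fit can be
#' performed on the log scale (`fit_scale = "log"`), with limits
#' log-transformed accordingly.
#'
#' @param values Numeric sample (simulated or manufacturing DS values), n >= 2.
#' @param spec A [quality_attribute()] or `list(lower=, upper=)` (NA for an
#'   absent side).
#' @param level Confidence level of the sd bound (default 0.80).
#' @param fit_scale `"raw"` (default) or `"log"`.
#' @param sided Sidedness of the sd confidence bound, `"one"` or `"two"`.
#' @return An object of class `"oos_result"` with fields `n`, `mean`, `sd`,
#'   `sd_upper80`, `oos_probability`, `degenerate` (zero sample sd) and the
#'   spec used.
#' @export
oos_probability <- function(values, spec, level = 0.80,
                            fit_scale = c("raw", "log"),
                            sided = c("one", "two")) {
  fit_scale <- match.arg(fit_scale)
  sided <- match.arg(sided)
  sp <- .as_spec(spec)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("oos_probability needs n >= 2 finite values")
  lo <- sp$lower; hi <- sp$upper
  if (is.na(lo) && is.na(hi)) stop("spec carries no limit")
  if (fit_scale == "log") {
    check_positive(values, "values (log-scale fit)")
    values <- log(values)
    if (!is.na(lo)) lo <- log(lo)
    if (!is.na(hi)) hi <- log(hi)
  }
  m <- mean(values); s <- stats::sd(values)
  degenerate <- s == 0
  s_u <- if (degenerate) 0 else upper_sd_ci(s, n, level, sided)
  if (degenerate) {
    oos <- (if (!is.na(hi)) as.numeric(m > hi) else 0) +
           (if (!is.na(lo)) as.numeric(m < lo) else 0)
    oos <- min(oos, 1)
  } else {
    oos <- (if (!is.na(hi)) stats::pnorm(hi, m, s_u, lower.tail = FALSE) else 0) +
           (if (!is.na(lo)) stats::pnorm(lo, m, s_u) else 0)
  }
  structure(list(n = n, mean = m, sd = s, sd_upper80 = s_u,
                 oos_probability = oos, spec = sp, scale_of_fit = fit_scale,
                 level = level, degenerate = degenerate),
            class = "oos_result")
}

#' @export
print.oos_result <- function(x, ...) {
  cat(sprintf("<oos_result> OOS = %.4g (n = %d, mean %.4g, sd %.4g -> %.4g, %s scale%s)\n",
              x$oos_probability, x$n, x$mean, x$sd, x$sd_upper80,
              x$scale_of_fit, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Conventional +/- 3 standard deviation limits
#'
#' The baseline the integrated-process-model criteria are compared against:
#' mean +/- 3 plain sample standard deviations of the historical data (no
#' confidence-bound inflation, no link to drug-substance specifications).
#'
#' @param values Numeric sample, n >= 2.
#' @return `c(lower, upper)`.
#' @export
three_sd_limits <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("three_sd_limits needs n >= 2")
  m <- mean(values); s <- stats::sd(values)
  c(lower = m - 3 * s, upper = m + 3 * s)
}

#' Plausibility check: simulation versus manufacturing runs
#'
#' Compares the simulated drug-substance distribution with actually
#' performed manufacturing runs at target conditions: density-normalized
#' histogram overlays (each integrating to 1), a standardized mean
#' difference and two-sample Kolmogorov-Smirnov statistic, and the OOS
#' probability of both samples. The verdict passes when the two OOS
#' probabilities are of the same order of magnitude (within a factor of
#' `oos_ratio`, or both negligible) and the locations agree
#' (|SMD| <= 1).
#'
#' @param sim_values Simulated DS values (or a `"simulation_result"`, in
#'   which case `cqa` selects the attribute).
#' @param mfg_values Manufacturing DS values.
#' @param spec A [quality_attribute()] or `list(lower=, upper=)`.
#' @param cqa CQA name when `sim_values` is a simulation result.
#' @param fit_scale Scale for the OOS normal fits.
#' @param oos_ratio Same-order criterion for the OOS comparison (default 10).
#' @param oos_floor Both OOS below this are treated as equal (default 1e-4).
#' @param bins Histogram bin count for the overlay data.
#' @return An object of class `"plausibility_report"`.
#' @export
plausibility_check <- function(sim_values, mfg_values, spec, cqa = NULL,
                               fit_scale = c("raw", "log"),
                               oos_ratio = 10, oos_floor = 1e-4, bins = 20L) {
  fit_scale <- match.arg(fit_scale)
  if (inherits(sim_values, "simulation_result")) {
    stopifnot(!is.null(cqa))
    sim_values <- sim_values$ds[[cqa]]
  }
  sim_values <- sim_values[is.finite(sim_values)]
  mfg_values <- mfg_values[is.finite(mfg_values)]
  stopifnot(length(sim_values) >= 2L, length(mfg_values) >= 2L)

  brk <- seq(min(sim_values, mfg_values), max(sim_values, mfg_values),
             length.out = bins + 1L)
  if (brk[1] == brk[length(brk)]) brk <- brk[1] + c(-0.5, 0.5)
  h_sim <- graphics::hist(sim_values, breaks = brk, plot = FALSE)
  h_mfg <- graphics::hist(mfg_values, breaks = brk, plot = FALSE)

  pooled_sd <- sqrt(((length(sim_values) - 1) * stats::var(sim_values) +
                     (length(mfg_values) - 1) * stats::var(mfg_values)) /
                    (length(sim_values) + length(mfg_values) - 2))
  smd <- if (pooled_sd > 0) (mean(sim_values) - mean(mfg_values)) / pooled_sd
         else 0
  ks <- suppressWarnings(stats::ks.test(sim_values, mfg_values))

  oos_sim <- oos_probability(sim_values, spec, fit_scale = fit_scale)
  oos_mfg <- oos_probability(mfg_values, spec, fit_scale = fit_scale)
  p1 <- oos_sim$oos_probability; p2 <- oos_mfg$oos_probability
  oos_ok <- (p1 <= oos_floor && p2 <= oos_floor) ||
    (max(p1, p2) / max(min(p1, p2), .Machine$double.xmin) <= oos_ratio)
  loc_ok <- abs(smd) <= 1
  structure(list(
    breaks = brk,
    density_sim = h_sim$density, density_mfg = h_mfg$density,
    smd = smd, ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    oos_sim = oos_sim, oos_mfg = oos_mfg,
    oos_ok = oos_ok, location_ok = loc_ok,
    pass = oos_ok && loc_ok
  ), class = "plausibility_report")
}

#' @export
print.plausibility_report <- function(x, ...) {
  cat(sprintf("<plausibility_report> %s\n",
              if (x$pass) "PASS" else "FLAG"))
  cat(sprintf("  SMD = %.3f%s, KS D = %.3f (p = %.3g)\n", x$smd,
              if (!x$location_ok) " [FLAG]" else "", x$ks_stat, x$ks_p))
  cat(sprintf("  OOS simulated = %.4g, manufacturing = %.4g%s\n",
              x$oos_sim$oos_probability, x$oos_mfg$oos_probability,
              if (!x$oos_ok) " [FLAG]" else ""))
  invisible(x)
}
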