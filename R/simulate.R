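# Monte-Carlo propagation of CQA values through the process chain.

#' Sample a process parameter from its normal operating range
#'
#' Draws operating values around the set-point: Normal(set-point,
#' cv * |set-point|) for `"normal"`; a variance-matched uniform
#' (half-width sqrt(3) * sd, preserving the stated CV) for `"uniform"`;
#' a normal truncated at +/- 3 sd (the conventional NOR coverage) for
#' `"truncated_normal"`.
#'
#' @param pp A [process_parameter()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
#' @examples
#' pp <- process_parameter("pH", 7, cv = 0.03)
#' summary(sample_nor(pp, 1000))
sample_nor <- function(pp, n = 1L) {
  stopifnot(inherits(pp, "process_parameter"))
  if (pp$set_point == 0) {
    stop("set-point of '", pp$name, "' is 0: a cv-based sd is undefined; ",
         "supply an absolute spread via the design range instead")
  }
  s <- pp$cv * abs(pp$set_point)
  switch(pp$distribution,
    normal = stats::rnorm(n, pp$set_point, s),
    uniform = stats::runif(n, pp$set_point - sqrt(3) * s,
                           pp$set_point + sqrt(3) * s),
    truncated_normal = {
      u <- stats::runif(n, stats::pnorm(-3), stats::pnorm(3))
      pp$set_point + s * stats::qnorm(u)
    })
}

.override_for <- function(config, cqa_name) {
  ov <- config$fixed_pool_overrides
  if (!length(ov)) return(NULL)
  keys <- names(ov)
  hit <- grepl(paste0(":", cqa_name, "$"), keys)
  if (!any(hit)) return(NULL)
  k <- keys[hit][1]
  list(uo = as.integer(sub(":.*$", "", k)), value = ov[[k]])
}

# Simulate n trajectories of one CQA through its modelled sub-range.
# The RNG state is taken as-is (callers seed it); vectorized across runs.
.sim_one_cqa <- function(chain, cqa_name, config, n) {
  cqa <- chain$cqas[[cqa_name]]
  r <- chain$ranges[[cqa_name]]
  uo_ids <- r[1]:r[2]
  pools <- matrix(NA_real_, n, length(uo_ids),
                  dimnames = list(NULL, as.character(uo_ids)))
  loads <- pools
  n_clamped <- 0L; n_capped <- 0L
  ov <- .override_for(config, cqa_name)
  if (!is.null(ov)) {
    if (!(ov$uo %in% uo_ids)) {
      stop("override UO ", ov$uo, " outside the modelled sub-range of '",
           cqa_name, "'")
    }
    check_positive(ov$value, "imposed pool value")
    load <- rep(ov$value, n)
    pools[, as.character(ov$uo)] <- ov$value
    start <- ov$uo + 1L
  } else {
    ini <- chain$init[[cqa_name]]
    load <- exp(stats::rnorm(n, ini$mean_log, ini$sd_log))
    start <- uo_ids[1]
  }
  if (start <= r[2]) for (k in start:r[2]) {
    uo <- chain$uos[[as.character(k)]]
    loads[, as.character(k)] <- load
    if (cqa_name %in% uo$fallback) {
      pool <- load  # no data: impurity assumed not to increase (pass-through)
    } else {
      model <- uo$models[[cqa_name]]
      pp_mat <- NULL
      if (inherits(model, c("doe_model", "combined_model"))) {
        pps <- uo$process_parameters
        pp_mat <- vapply(pps, sample_nor, numeric(n), n = n)
        pp_mat <- matrix(pp_mat, nrow = n,
                         dimnames = list(NULL, vapply(pps, `[[`,
                                                      character(1), "name")))
      }
      perf <- .draw_perf(model, pp = pp_mat, slc = load, n = n,
                         sampling = config$sampling,
                         pi_level = config$pi_level)
      n_clamped <- n_clamped + attr(perf, "n_clamped")
      perf <- as.numeric(perf)
      pool <- if (cqa$direction == "impurity") load / perf else load * perf
    }
    pool[!is.finite(pool) | pool <= 0] <- NA_real_
    if (cqa$percent) {
      over <- !is.na(pool) & pool > 100
      n_capped <- n_capped + sum(over)
      pool[over] <- 100
    }
    pools[, as.character(k)] <- pool
    load <- pool
  }
  ds <- pools[, ncol(pools)]
  list(pools = pools, loads = loads, ds = ds, n_clamped = n_clamped,
       n_capped = n_capped, n_aborted = sum(!is.finite(ds)))
}

#' Run the integrated process model Monte-Carlo simulation
#'
#' Simulates `config$n_runs` independent process runs per CQA: the initial
#' load is drawn from the CQA's chain-entry lognormal distribution, and at
#' each unit operation process parameters are sampled from their normal
#' operating ranges, a performance value is drawn from the step's model, and
#' the pool is computed as load / SC (impurities) or load * Y (purities);
#' the pool becomes the next step's load. The distribution at the last
#' modelled unit operation is the drug-substance distribution. Percent-type
#' CQAs are capped at 100 (counted). Runs producing non-finite values are
#' aborted and counted, not resampled; more than 10% aborts is a hard error.
#' Results are bit-for-bit reproducible for a fixed `config$seed`.
#'
#' @param chain A validated [process_chain()].
#' @param config A [sim_config()]; `fixed_pool_overrides` entries named
#'   `"<uo_id>:<cqa>"` impose a pool value at that unit operation and start
#'   the simulation there (the sensitivity-analysis hook).
#' @param cqa Optional character vector of CQA names (default: all).
#' @return An object of class `"simulation_result"`: per-CQA pool matrices
#'   (`run x UO`), drug-substance vectors `ds`, clamp/cap/abort counts and
#'   the configuration echo.
#' @export
ipm_simulate <- function(chain, config = sim_config(), cqa = NULL) {
  validate_chain(chain)
  cqa <- if (is.null(cqa)) names(chain$cqas) else match.arg(cqa,
    names(chain$cqas), several.ok = TRUE)
  out <- list()
  for (i in seq_along(cqa)) {
    cq <- cqa[i]
    set.seed(derive_seed(config$seed, match(cq, names(chain$cqas))))
    res <- .sim_one_cqa(chain, cq, config, config$n_runs)
    if (res$n_aborted > 0.10 * config$n_runs) {
      stop(sprintf(
        "CQA '%s': %d of %d simulated runs aborted (>10%%) — model/config inconsistency",
        cq, res$n_aborted, config$n_runs))
    }
    out[[cq]] <- res
  }
  structure(list(
    cqas = cqa,
    pools = lapply(out, `[[`, "pools"),
    ds = lapply(out, `[[`, "ds"),
    n_clamped = vapply(out, `[[`, integer(1), "n_clamped"),
    n_capped = vapply(out, `[[`, integer(1), "n_capped"),
    n_aborted = vapply(out, `[[`, integer(1), "n_aborted"),
    config = config
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d runs, seed %d\n",
              x$config$n_runs, x$config$seed))
  for (cq in x$cqas) {
    d <- x$ds[[cq]]
    cat(sprintf("  %s: DS median %.4g (IQR %.4g-%.4g), clamped %d, capped %d, aborted %d\n",
                cq, stats::median(d, na.rm = TRUE),
                stats::quantile(d, 0.25, na.rm = TRUE),
                stats::quantile(d, 0.75, na.rm = TRUE),
                x$n_clamped[[cq]], x$n_capped[[cq]], x$n_aborted[[cq]]))
  }
  invisible(x)
}

#' Simulate a single process run
#'
#' One trajectory of a CQA through its modelled sub-range: per-UO pool
#' values, ending at drug substance. Mainly a readable wrapper around the
#' vectorized engine for inspection and testing.
#'
#' @inheritParams ipm_simulate
#' @param cqa Name of one CQA.
#' @return Named numeric vector of pool values (names = UO ids).
#' @export
simulate_run <- function(chain, cqa, config = sim_config()) {
  validate_chain(chain)
  stopifnot(cqa %in% names(chain$cqas))
  set.seed(derive_seed(config$seed, match(cqa, names(chain$cqas))))
  res <- .sim_one_cqa(chain, cqa, config, 1L)
  res$pools[1L, ]
}

#' Convergence scan over the number of Monte-Carlo cycles
#'
#' Quantifies how stable the drug-substance distribution summary is as a
#' function of the number of simulation runs: for each cycle count,
#' `n_repeats` independent simulations are performed and the across-repeat
#' variance of the DS median and of its mean absolute deviation (MAD) is
#' reported. A plateau (no severe change) justifies the default of 800 runs.
#'
#' @param chain A [process_chain()].
#' @param cqa Name of the CQA to scan.
#' @param cycles Integer vector of run counts (typically within 50–1200).
#' @param n_repeats Independent repeats per cycle count (>= 10).
#' @param config Base [sim_config()]; its seed anchors all repeats.
#' @param center If `TRUE`, additionally returns mean-centered variances
#'   (visualization parity with published convergence plots).
#' @return Data frame with columns `cycles`, `var_median`, `var_mad` (and
#'   centered counterparts when `center = TRUE`).
#' @export
convergence_scan <- function(chain, cqa, cycles = c(50L, 100L, 200L, 400L,
                                                    800L, 1200L),
                             n_repeats = 20L, config = sim_config(),
                             center = FALSE) {
  stopifnot(n_repeats >= 2L, all(cycles >= 1L))
  var_med <- var_mad <- numeric(length(cycles))
  for (i in seq_along(cycles)) {
    meds <- mads <- numeric(n_repeats)
    for (j in seq_len(n_repeats)) {
      cfg <- config
      cfg$n_runs <- as.integer(cycles[i])
      cfg$seed <- derive_seed(config$seed, cycles[i], j)
      sim <- ipm_simulate(chain, cfg, cqa = cqa)
      d <- sim$ds[[cqa]]
      meds[j] <- stats::median(d, na.rm = TRUE)
      mads[j] <- stats::mad(d, na.rm = TRUE)
    }
    var_med[i] <- stats::var(meds)
    var_mad[i] <- stats::var(mads)
  }
  out <- data.frame(cycles = cycles, var_median = var_med, var_mad = var_mad)
  if (center) {
    out$var_median_centered <- var_med - mean(var_med)
    out$var_mad_centered <- var_mad - mean(var_mad)
  }
  out
}
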