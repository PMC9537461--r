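# Process-chain containers: unit operations, the ordered chain, and the
# Monte-Carlo simulation configuration.

#' Define a unit operation
#'
#' One step of the purification chain, holding its process parameters and
#' one performance model per monitored CQA. A CQA may instead carry the
#' fallback flag `iac_equals_ds_spec` (no usable data, e.g. all measurements
#' at the limit of quantification): the step is then treated as
#' pass-through during simulation and its acceptance criterion is set equal
#' to the drug-substance specification limit.
#'
#' @param id 1-based integer position along the chain.
#' @param name Human-readable step name.
#' @param process_parameters List of [process_parameter()] objects.
#' @param models Named list (by CQA name) of fitted models: `"doe_model"`,
#'   `"sc_model"`, `"manufacturing_sc"` or `"combined_model"`.
#' @param fallback Character vector of CQA names flagged `iac_equals_ds_spec`.
#' @return An object of class `"unit_operation"`.
#' @export
unit_operation <- function(id, name, process_parameters = list(),
                           models = list(), fallback = character(0)) {
  stopifnot(is.numeric(id), id >= 1, is.character(name))
  ok <- vapply(models, inherits, logical(1),
               what = c("doe_model", "sc_model", "manufacturing_sc",
                        "combined_model"))
  if (length(models) && !all(ok)) {
    stop("unknown model type for CQA(s): ",
         paste(names(models)[!ok], collapse = ", "))
  }
  both <- intersect(names(models), fallback)
  if (length(both)) {
    stop("CQA(s) both modelled and flagged iac_equals_ds_spec: ",
         paste(both, collapse = ", "))
  }
  structure(list(id = as.integer(id), name = name,
                 process_parameters = process_parameters,
                 models = models, fallback = fallback),
            class = "unit_operation")
}

#' Assemble an integrated process chain
#'
#' Orders the unit operations, attaches the CQA definitions, each CQA's
#' modelled sub-range of the chain (CQAs are only modelled where they are
#' measured in both load and pool), and the initial (chain-entry) load
#' distribution per CQA, taken as lognormal fitted to manufacturing data.
#'
#' @param uos List of [unit_operation()] objects with strictly increasing ids.
#' @param cqas List of [quality_attribute()] objects.
#' @param ranges Named list (by CQA name) of `c(first_uo, last_uo)` modelled
#'   sub-ranges; defaults to the full chain for every CQA.
#' @param init Named list (by CQA name) of `list(mean_log, sd_log)` initial
#'   load distributions.
#' @return An object of class `"process_chain"`.
#' @export
process_chain <- function(uos, cqas, ranges = NULL, init) {
  stopifnot(length(uos) >= 1L, length(cqas) >= 1L)
  ids <- vapply(uos, `[[`, integer(1), "id")
  if (any(diff(ids) <= 0)) stop("unit-operation ids must be strictly increasing")
  names(uos) <- as.character(ids)
  cqa_names <- vapply(cqas, `[[`, character(1), "name")
  names(cqas) <- cqa_names
  if (is.null(ranges)) {
    ranges <- stats::setNames(rep(list(range(ids)), length(cqas)), cqa_names)
  }
  chain <- structure(list(uos = uos, cqas = cqas, ranges = ranges,
                          init = init),
                     class = "process_chain")
  validate_chain(chain)
  chain
}

#' Validate a process chain
#'
#' Checks the structural invariants: contiguous modelled sub-ranges inside
#' the chain, an initial load distribution for every modelled CQA, and — for
#' every unit operation inside a CQA's sub-range — exactly one model entry
#' or the `iac_equals_ds_spec` fallback flag.
#'
#' @param chain A [process_chain()].
#' @return The chain, invisibly; errors list all violations at once.
#' @export
validate_chain <- function(chain) {
  errs <- character(0)
  ids <- vapply(chain$uos, `[[`, integer(1), "id")
  for (cq in names(chain$cqas)) {
    r <- chain$ranges[[cq]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2]) {
      errs <- c(errs, sprintf("CQA '%s': invalid modelled sub-range", cq))
      next
    }
    if (!all(r %in% ids)) {
      errs <- c(errs, sprintf("CQA '%s': sub-range [%d, %d] outside chain",
                              cq, r[1], r[2]))
      next
    }
    if (is.null(chain$init[[cq]])) {
      errs <- c(errs, sprintf("CQA '%s': missing initial load distribution", cq))
    }
    for (k in r[1]:r[2]) {
      uo <- chain$uos[[as.character(k)]]
      has_model <- cq %in% names(uo$models)
      has_flag <- cq %in% uo$fallback
      if (!has_model && !has_flag) {
        errs <- c(errs, sprintf(
          "UO %d ('%s'): no model or fallback flag for CQA '%s'", k, uo$name, cq))
      }
    }
  }
  if (length(errs)) stop("invalid process chain:\n  ",
                         paste(errs, collapse = "\n  "), call. = FALSE)
  invisible(chain)
}

#' @export
print.process_chain <- function(x, ...) {
  cat(sprintf("<process_chain> %d unit operations, %d CQA(s)\n",
              length(x$uos), length(x$cqas)))
  for (cq in names(x$cqas)) {
    r <- x$ranges[[cq]]
    cat(sprintf("  %s: modelled UO %d..%d\n", cq, r[1], r[2]))
  }
  invisible(x)
}

#' Monte-Carlo simulation configuration
#'
#' @param n_runs Number of simulated process runs (default 800, the point
#'   beyond which the median and MAD of the drug-substance distribution are
#'   stable in the convergence scan).
#' @param seed Master seed; all sub-streams are derived from it.
#' @param pi_level Prediction-interval level (default 0.95).
#' @param sampling Prediction-error sampling: `"predictive_t"` or
#'   `"truncated_95"` (see [predict_performance()]).
#' @param oos_threshold OOS-probability threshold defining the acceptance
#'   criteria (default 0.05).
#' @param fit_scale Default scale for the normal fit in OOS estimation,
#'   `"raw"` or `"log"`; per-CQA `fit_scale` takes precedence.
#' @param fixed_pool_overrides Named list `"uo:cqa" -> value` of imposed pool
#'   values (the parameter-sensitivity-analysis hook).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_runs = 800L, seed = 1L, pi_level = 0.95,
                       sampling = c("predictive_t", "truncated_95"),
                       oos_threshold = 0.05,
                       fit_scale = c("raw", "log"),
                       fixed_pool_overrides = list()) {
  sampling <- match.arg(sampling)
  fit_scale <- match.arg(fit_scale)
  stopifnot(n_runs >= 1, pi_level > 0, pi_level < 1,
            oos_threshold > 0, oos_threshold < 1)
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 pi_level = pi_level, sampling = sampling,
                 oos_threshold = oos_threshold, fit_scale = fit_scale,
                 fixed_pool_overrides = fixed_pool_overrides),
            class = "sim_config")
}
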