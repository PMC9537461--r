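# Dataset readers/writers and the structured process configuration.
#
# Manufacturing CSV: batch_id, uo_id, cqa, load_value, pool_value, scale.
# Values at an assay's limit of quantification are encoded "<LOQ:x".
# DoE CSV: '#'-prefixed metadata lines (starting-material SLC per CQA,
# design type, UO id, factor list) followed by run_id, factor columns in
# native units, response_<cqa> columns and scale.
# Process config: JSON (schema-validated, all violations listed at once).

.parse_loq <- function(x, column, errors) {
  x <- trimws(as.character(x))
  loq <- grepl("^<LOQ:", x)
  num <- suppressWarnings(as.numeric(ifelse(loq, sub("^<LOQ:", "", x), x)))
  bad <- !is.finite(num) | num <= 0
  if (any(bad)) {
    errors(sprintf("column %s: non-positive or unparseable value(s) in row(s) %s",
                   column, paste(utils::head(which(bad), 5L), collapse = ", ")))
  }
  list(value = num, loq = loq)
}

#' Read a manufacturing dataset
#'
#' Strictly validated CSV with columns `batch_id`, `uo_id`, `cqa`,
#' `load_value`, `pool_value`, `scale`. `"<LOQ:x"` markers are parsed into
#' numeric values with logical `load_loq`/`pool_loq` flag columns; all-LoQ
#' groups drive the `iac_equals_ds_spec` fallback downstream.
#'
#' @param path CSV file path.
#' @return Data frame with numeric values and LoQ flags.
#' @export
read_manufacturing_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  errs <- character(0)
  errors <- function(msg) errs <<- c(errs, msg)
  need <- c("batch_id", "uo_id", "cqa", "load_value", "pool_value", "scale")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!nrow(df)) stop("empty manufacturing dataset: ", path)
  lv <- .parse_loq(df$load_value, "load_value", errors)
  pv <- .parse_loq(df$pool_value, "pool_value", errors)
  uo <- suppressWarnings(as.integer(df$uo_id))
  if (any(is.na(uo))) errors("uo_id must be integer")
  if (!all(df$scale %in% c("small", "manufacturing"))) {
    errors("scale must be 'small' or 'manufacturing'")
  }
  key <- paste(df$batch_id, df$uo_id, df$cqa)
  if (anyDuplicated(key)) {
    errors(sprintf("duplicate (batch, uo, cqa) row(s): %s",
                   paste(utils::head(unique(key[duplicated(key)]), 3L),
                         collapse = "; ")))
  }
  if (length(errs)) stop("invalid manufacturing dataset:\n  ",
                         paste(errs, collapse = "\n  "), call. = FALSE)
  data.frame(batch_id = df$batch_id, uo_id = uo, cqa = df$cqa,
             load_value = lv$value, pool_value = pv$value,
             scale = df$scale, load_loq = lv$loq, pool_loq = pv$loq,
             stringsAsFactors = FALSE)
}

#' Write a manufacturing dataset
#'
#' Inverse of [read_manufacturing_csv()]; LoQ-flagged values are rendered as
#' `"<LOQ:x"` markers so the round trip is lossless.
#'
#' @param data Data frame as returned by [generate_manufacturing_runs()] or
#'   [read_manufacturing_csv()].
#' @param path Output path.
#' @export
write_manufacturing_csv <- function(data, path) {
  fmt <- function(v, flag) {
    flag <- rep_len(flag, length(v))
    ifelse(flag, paste0("<LOQ:", format(v, digits = 15)),
           format(v, digits = 15))
  }
  out <- data.frame(batch_id = data$batch_id, uo_id = data$uo_id,
                    cqa = data$cqa,
                    load_value = fmt(data$load_value,
                                     data$load_loq %||% FALSE),
                    pool_value = fmt(data$pool_value,
                                     data$pool_loq %||% FALSE),
                    scale = data$scale, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a DoE dataset
#'
#' Serializes a [generate_doe()] data frame: `#`-prefixed metadata lines
#' (starting-material specific load concentration per CQA, design type,
#' UO id, factor list) followed by the run table.
#'
#' @param data DoE data frame with `slc`, `factors`, `design`, `uo_id`
#'   attributes.
#' @param path Output path.
#' @export
write_doe_csv <- function(data, path) {
  slc <- attr(data, "slc")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#uo_id,", attr(data, "uo_id")),
    paste0("#design,", attr(data, "design")),
    paste0("#factors,", paste(attr(data, "factors"), collapse = ",")),
    vapply(names(slc)[is.finite(slc)], function(cq)
      paste0("#slc,", cq, ",", format(slc[[cq]], digits = 15)), character(1))
  ), con)
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DoE dataset
#'
#' @param path Path written by [write_doe_csv()].
#' @return Data frame with `slc`, `factors`, `design`, `uo_id` attributes
#'   restored.
#' @export
read_doe_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("empty DoE dataset: ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  slc <- numeric(0)
  for (m in meta) {
    parts <- strsplit(sub("^#", "", m), ",")[[1]]
    if (parts[1] == "slc") slc[parts[2]] <- as.numeric(parts[3])
    if (parts[1] == "design") attr(df, "design") <- parts[2]
    if (parts[1] == "uo_id") attr(df, "uo_id") <- as.integer(parts[2])
    if (parts[1] == "factors") attr(df, "factors") <- parts[-1]
  }
  attr(df, "slc") <- slc
  resp <- grep("^response_", names(df), value = TRUE)
  for (col in c(attr(df, "factors"), resp)) {
    if (any(!is.finite(df[[col]]))) stop("non-numeric entries in column ", col)
  }
  df
}

# -- process configuration --------------------------------------------------

#' Load and validate a process configuration
#'
#' Reads the JSON process description: CQA definitions with drug-substance
#' specification limits, ordered unit operations with process-parameter
#' set-points / CVs / design ranges, per-CQA model-type assignments,
#' modelled sub-ranges and simulation defaults (cv 0.03, 800 runs, 95%
#' prediction interval, 5% OOS threshold). All schema violations are
#' reported at once with their field paths.
#'
#' @param path JSON file path.
#' @return A validated config list (class `"ipm_config"`), ready for
#'   [fit_process()].
#' @export
load_process_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  errs <- character(0)
  err <- function(...) errs <<- c(errs, paste0(...))
  if (is.null(cfg$cqas) || !length(cfg$cqas)) err("cqas: at least one CQA required")
  cqa_names <- vapply(cfg$cqas, function(x) x$name %||% NA_character_,
                      character(1))
  for (i in seq_along(cfg$cqas)) {
    cq <- cfg$cqas[[i]]
    if (is.null(cq$name)) err("cqas[", i, "].name missing")
    if (is.null(cq$direction) || !cq$direction %in% c("impurity", "purity")) {
      err("cqas[", i, "].direction must be 'impurity' or 'purity'")
    }
    if (is.null(cq$ds_spec)) err("cqas[", i, "].ds_spec: missing specification limit")
  }
  known_types <- c("doe", "sc", "manufacturing_sc", "combined",
                   "ds_spec_fallback")
  if (is.null(cfg$uos) || !length(cfg$uos)) err("uos: at least one unit operation required")
  for (i in seq_along(cfg$uos)) {
    uo <- cfg$uos[[i]]
    if (is.null(uo$id)) err("uos[", i, "].id missing")
    for (pp in uo$pps %||% list()) {
      if (is.null(pp$name) || is.null(pp$set_point)) {
        err("uos[", i, "].pps: name and set_point required")
      }
    }
    for (cq in names(uo$models %||% list())) {
      m <- uo$models[[cq]]
      ty <- m$type %||% NA_character_
      if (!ty %in% known_types) {
        err("uos[", i, "].models.", cq, ".type: unknown model type '", ty, "'")
      }
      if (!cq %in% cqa_names) {
        err("uos[", i, "].models.", cq, ": CQA not declared")
      }
      if (isTRUE(ty %in% c("doe", "combined"))) {
        fac <- unlist(m$factors)
        ppn <- vapply(uo$pps %||% list(), function(p) p$name, character(1))
        for (f in fac) {
          p <- uo$pps[[match(f, ppn)]]
          if (is.na(match(f, ppn)) || is.null(p$design_range)) {
            err("uos[", i, "].models.", cq, ": DoE factor '", f,
                "' has no process parameter with a design_range")
          }
        }
      }
    }
  }
  if (length(errs)) stop("invalid process config:\n  ",
                         paste(errs, collapse = "\n  "), call. = FALSE)
  sim <- cfg$simulation %||% list()
  cfg$simulation <- list(
    n_runs = as.integer(sim$n_runs %||% 800L),
    pi_level = sim$pi_level %||% 0.95,
    oos_threshold = sim$oos_threshold %||% 0.05,
    seed = as.integer(sim$seed %||% 1L))
  structure(cfg, class = "ipm_config")
}

#' Write a process configuration
#'
#' @param cfg An `"ipm_config"` list (as loaded, or hand-built).
#' @param path Output JSON path.
#' @export
write_process_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.cqa_from_config <- function(cq) {
  quality_attribute(cq$name, cq$direction, cq$unit %||% "ng/mg",
                    ds_spec = cq$ds_spec,
                    ds_spec_second = cq$ds_spec_second %||% NA_real_,
                    fit_scale = cq$fit_scale %||% "raw")
}

.pp_from_config <- function(pp) {
  process_parameter(pp$name, pp$set_point, cv = pp$cv %||% 0.03,
                    distribution = pp$distribution %||% "normal",
                    design_range = if (!is.null(pp$design_range))
                      unlist(pp$design_range))
}

# Performance values (SC or yield) for one UO x CQA from manufacturing data,
# applying the LoQ policy: all-LoQ -> NULL (fallback), partial LoQ -> value/2
# with a warning.
.mfg_performance <- function(mfg, uo_id, cqa, response_kind) {
  sel <- mfg$uo_id == uo_id & mfg$cqa == cqa
  d <- mfg[sel, , drop = FALSE]
  if (!nrow(d)) return(NULL)
  llq <- rep_len(d$load_loq %||% FALSE, nrow(d))
  plq <- rep_len(d$pool_loq %||% FALSE, nrow(d))
  loq <- llq | plq
  if (all(loq)) return(NULL)
  if (any(loq)) {
    warning("UO ", uo_id, " / ", cqa, ": ", sum(loq),
            " partially quantified record(s); substituting LOQ/2")
    d$load_value[llq] <- d$load_value[llq] / 2
    d$pool_value[plq] <- d$pool_value[plq] / 2
  }
  d$performance <- if (response_kind == "specific_clearance") {
    compute_specific_clearance(d$load_value, d$pool_value)
  } else {
    compute_yield(d$load_value, d$pool_value)
  }
  d
}

#' Fit a complete process chain from configuration and data
#'
#' Builds the integrated process model: for every unit operation and CQA the
#' configured model type is fitted from the manufacturing dataset (SC and
#' manufacturing-distribution models) and/or the matching DoE dataset (DoE
#' and combined models). CQA groups whose measurements all sit at the limit
#' of quantification are demoted to the `iac_equals_ds_spec` fallback with a
#' warning. The chain-entry load distribution per CQA is a lognormal fitted
#' to the load values at the first modelled unit operation (unless given in
#' the config).
#'
#' @param cfg An `"ipm_config"` from [load_process_config()].
#' @param mfg_data Manufacturing data frame ([read_manufacturing_csv()]).
#' @param doe_data Named list of DoE data frames keyed by UO id (as
#'   character), e.g. `list("6" = read_doe_csv(...))`.
#' @return List with the fitted `chain` ([process_chain()]) and the
#'   simulation `config` ([sim_config()]).
#' @export
fit_process <- function(cfg, mfg_data, doe_data = list()) {
  stopifnot(inherits(cfg, "ipm_config"))
  cqas <- lapply(cfg$cqas, .cqa_from_config)
  names(cqas) <- vapply(cqas, `[[`, character(1), "name")

  fit_doe_part <- function(uo_id, cq_name, mspec, pps) {
    key <- as.character(uo_id)
    doe <- doe_data[[key]]
    if (is.null(doe)) stop("UO ", uo_id, ": DoE model configured for '",
                           cq_name, "' but no DoE dataset supplied")
    factors <- unlist(mspec$factors) %||% attr(doe, "factors")
    ranges <- lapply(factors, function(f) {
      pp <- Filter(function(p) p$name == f, pps)[[1]]
      unlist(pp$design_range)
    })
    names(ranges) <- factors
    fit_doe_model(doe, factors, paste0("response_", cq_name),
                  design_ranges = ranges,
                  design = mspec$design %||% attr(doe, "design") %||% "auto",
                  cqa = cqas[[cq_name]],
                  response_kind = mspec$response_kind %||%
                    if (cqas[[cq_name]]$direction == "purity") "yield"
                    else "specific_clearance",
                  slc_doe = unname(attr(doe, "slc")[cq_name] %||% NA_real_))
  }

  uos <- lapply(cfg$uos, function(uo) {
    pps <- lapply(uo$pps %||% list(), .pp_from_config)
    models <- list()
    fallback <- unlist(uo$fallback) %||% character(0)
    for (cq_name in names(uo$models %||% list())) {
      mspec <- uo$models[[cq_name]]
      cq <- cqas[[cq_name]]
      kind <- mspec$response_kind %||%
        if (cq$direction == "purity") "yield" else "specific_clearance"
      if (identical(mspec$type, "ds_spec_fallback")) {
        fallback <- c(fallback, cq_name)
        next
      }
      d <- .mfg_performance(mfg_data, uo$id, cq_name, kind)
      if (mspec$type %in% c("sc", "manufacturing_sc", "combined") &&
          is.null(d)) {
        warning("UO ", uo$id, " / ", cq_name, ": no quantified manufacturing ",
                "data (all at LOQ?); falling back to iac_equals_ds_spec")
        fallback <- c(fallback, cq_name)
        next
      }
      models[[cq_name]] <- switch(mspec$type,
        manufacturing_sc = fit_manufacturing_sc(d$performance, cqa = cq,
                                                response_kind = kind),
        sc = fit_sc_model(d, cqa = cq, response_kind = kind),
        doe = fit_doe_part(uo$id, cq_name, mspec, uo$pps),
        combined = combined_model(
          fit_doe_part(uo$id, cq_name, mspec, uo$pps),
          fit_sc_model(d, cqa = cq, response_kind = kind)))
    }
    unit_operation(uo$id, uo$name %||% paste0("UO", uo$id), pps, models,
                   fallback = unique(fallback))
  })

  ranges <- lapply(cfg$ranges, function(r) as.integer(unlist(r)))
  init <- cfg$init
  if (is.null(init)) {
    init <- list()
    for (cq_name in names(cqas)) {
      first <- ranges[[cq_name]][1]
      sel <- mfg_data$uo_id == first & mfg_data$cqa == cq_name &
        !(mfg_data$load_loq %||% FALSE)
      lv <- mfg_data$load_value[sel]
      if (length(lv) < 2L) stop("cannot fit initial load distribution for '",
                                cq_name, "': too few records at UO ", first)
      init[[cq_name]] <- list(mean_log = mean(log(lv)),
                              sd_log = stats::sd(log(lv)))
    }
  } else {
    init <- lapply(init, function(x) list(mean_log = x$mean_log,
                                          sd_log = x$sd_log))
  }
  chain <- process_chain(uos, cqas, ranges = ranges, init = init)
  sim <- sim_config(n_runs = cfg$simulation$n_runs,
                    seed = cfg$simulation$seed,
                    pi_level = cfg$simulation$pi_level,
                    oos_threshold = cfg$simulation$oos_threshold)
  list(chain = chain, config = sim)
}

# -- result export ----------------------------------------------------------

#' Export simulation results
#'
#' Writes the tidy per-run pool table (`run`, `uo_id`, `cqa`, `pool_value`)
#' and a JSON summary (per-CQA DS mean/sd/quantiles, clamp/cap/abort counts,
#' seed).
#'
#' @param sim A `"simulation_result"`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_simulation_result <- function(sim, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    rows <- list()
    for (cq in sim$cqas) {
      p <- sim$pools[[cq]]
      rows[[cq]] <- data.frame(
        run = rep(seq_len(nrow(p)), ncol(p)),
        uo_id = rep(as.integer(colnames(p)), each = nrow(p)),
        cqa = cq, pool_value = as.vector(p), stringsAsFactors = FALSE)
    }
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summ <- lapply(sim$cqas, function(cq) {
      d <- sim$ds[[cq]]
      list(mean = mean(d, na.rm = TRUE), sd = stats::sd(d[is.finite(d)]),
           quantiles = as.list(stats::setNames(
             stats::quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95),
                             na.rm = TRUE),
             c("q05", "q25", "q50", "q75", "q95"))),
           n_clamped = sim$n_clamped[[cq]], n_capped = sim$n_capped[[cq]],
           n_aborted = sim$n_aborted[[cq]])
    })
    names(summ) <- sim$cqas
    jsonlite::write_json(list(seed = sim$config$seed,
                              n_runs = sim$config$n_runs, cqas = summ),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(sim)
}

#' Write the acceptance-criteria table
#'
#' @param table Output of [derive_all_iacs()] or [compare_3sd()].
#' @param path CSV path.
#' @export
write_iac_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what would be needed to reproduce a pipeline invocation
#' bit-for-bit: input-file digests, master seed, package version, per-stage
#' timings and all surfaced warnings.
#'
#' @param path Output JSON path.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param seed Master seed.
#' @param timings Named numeric vector of per-stage elapsed seconds.
#' @param warnings Character vector of surfaced warnings.
#' @export
write_manifest <- function(path, inputs = character(0), seed = NA_integer_,
                           timings = numeric(0), warnings = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(
    package = "ipmiac",
    version = as.character(utils::packageVersion("ipmiac")),
    seed = seed, input_digests = digests,
    timings_sec = as.list(timings),
    warnings = as.list(warnings)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
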