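# Synthetic processes with known ground truth.
#
# No public dataset exists for a full downstream purification chain with
# paired load/pool CQA measurements, so the package ships a generator that
# emulates the structure of a typical 9-unit-operation monoclonal-antibody
# downstream process: ~10 manufacturing runs per unit operation, OFAT /
# 11-run 5x3 / 17-run face-centered-central-composite DoEs, a host-cell-
# protein-like impurity spanning four decades, an aggregate-like percent
# impurity and a monomer-like percent purity. All generating models are
# explicit, so parameter recovery and propagation can be verified against
# closed forms.

# -- constructors for ground-truth model objects ----------------------------

# SC model with known intercept/slope; the design summary is synthesized
# from n log-loads spread around the typical load so prediction variance is
# realistic.
.make_sc_model <- function(a, b, slc_center, resid_sd, n = 10L,
                           spread_log = 0.4, cqa = NULL,
                           response_kind = "specific_clearance") {
  a <- unname(a); b <- unname(b); slc_center <- unname(slc_center)
  x <- seq(log(slc_center) - spread_log, log(slc_center) + spread_log,
           length.out = n)
  X <- cbind(`(Intercept)` = 1, log_slc = x)
  XtXinv <- chol2inv(qr.R(qr(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  structure(list(cqa = cqa, response_kind = response_kind,
                 coef = c(`(Intercept)` = a, log_slc = b), XtXinv = XtXinv,
                 residual_sd = resid_sd, dof = n - 2L,
                 p_slope = 0, significant = TRUE,
                 train_range = exp(range(x)),
                 residuals = NULL, fitted = NULL, n = n),
            class = "sc_model")
}

# Coded design matrices of the three supported experimental designs.
.coded_design <- function(design, k, n_center = 3L) {
  switch(design,
    ofat = {
      stopifnot(k == 1L)
      matrix(c(-1, -0.5, 0, 0.5, 1), ncol = 1)
    },
    grid5x3 = {
      stopifnot(k == 2L)
      g <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1)))
      rbind(g, c(-0.5, 0), c(0.5, 0))           # 11 runs, 5 x 3 levels
    },
    ccf = {
      stopifnot(k == 3L)
      corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
      faces <- rbind(diag(3), -diag(3))
      centers <- matrix(0, n_center, 3)
      rbind(corners, faces, centers)            # 8 + 6 + n_center runs
    },
    stop("unknown design '", design, "'"))
}

# DoE model with known coefficients. `coef` is a named vector whose first
# element is the intercept; remaining names are term labels over `factors`.
.make_doe_model <- function(coef, factors, design_ranges, design,
                            resid_sd, slc_doe = NA_real_, n_center = 3L,
                            cqa = NULL,
                            response_kind = "specific_clearance") {
  Zc <- .coded_design(design, length(factors), n_center)
  colnames(Zc) <- factors
  terms <- setdiff(names(coef), "(Intercept)")
  Xt <- if (length(terms)) {
    m <- vapply(terms, .term_column, numeric(nrow(Zc)), Z = Zc)
    matrix(m, nrow = nrow(Zc), dimnames = list(NULL, terms))
  } else NULL
  X <- cbind(`(Intercept)` = rep(1, nrow(Zc)), Xt)
  XtXinv <- chol2inv(qr.R(qr(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  structure(list(cqa = cqa, response_kind = response_kind,
                 terms = terms, coef = coef, XtXinv = XtXinv,
                 residual_sd = resid_sd, dof = nrow(Zc) - ncol(X),
                 p_values = stats::setNames(rep(0, length(coef)), names(coef)),
                 factors = factors, design_ranges = design_ranges,
                 design = design, has_scale = FALSE, slc_doe = slc_doe,
                 residuals = NULL, fitted = NULL, n = nrow(Zc),
                 selection = list(truth = TRUE)),
            class = "doe_model")
}

# -- oracle chain -----------------------------------------------------------

#' A minimal chain with closed-form behaviour
#'
#' An impurity chain in which every unit operation is a pure lognormal
#' clearance distribution, so the drug-substance log-value is exactly
#' normal: `log DS ~ N(m0 - sum(mk), sqrt(s0^2 + sum(sk^2)))`. Used as the
#' independent oracle for the simulation engine, the OOS estimator and the
#' acceptance-criteria inversion (see [analytic_chain_oracle()]).
#'
#' @param n_uos Number of unit operations (1–4 use the tabulated parameters;
#'   larger chains append generic steps).
#' @return A [process_chain()] with one impurity CQA `"imp"` (upper DS limit
#'   10 ng/mg, OOS fitted on the log scale).
#' @export
make_oracle_chain <- function(n_uos = 4L) {
  stopifnot(n_uos >= 1L)
  m <- c(1.6, 1.5, 1.4, 1.3); s <- c(0.15, 0.10, 0.12, 0.08)
  if (n_uos > 4L) { m <- c(m, rep(1.2, n_uos - 4L)); s <- c(s, rep(0.1, n_uos - 4L)) }
  m <- m[seq_len(n_uos)]; s <- s[seq_len(n_uos)]
  cqa <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 10,
                           fit_scale = "log")
  uos <- lapply(seq_len(n_uos), function(k) {
    unit_operation(k, paste0("UO", k),
                   models = list(imp = manufacturing_sc(m[k], s[k], n = 10L,
                                                        cqa = cqa)))
  })
  process_chain(uos, list(cqa),
                ranges = list(imp = c(1L, n_uos)),
                init = list(imp = list(mean_log = log(2000), sd_log = 0.2)))
}

#' Closed-form results for a lognormal-only chain
#'
#' For a chain in which every model of the CQA's sub-range is a
#' `manufacturing_sc` distribution (pass-through fallback steps count as
#' zero clearance with zero variance), the drug-substance log-value is
#' exactly normal and the OOS probability and the acceptance-criterion
#' inversion have closed forms. With `imposed_pool` at `uo_id` the
#' propagation starts there (mean `log(imposed_pool)`, sd 0), mirroring the
#' sensitivity-analysis override.
#'
#' @param chain A [process_chain()] of `manufacturing_sc` models only.
#' @param cqa CQA name (default: the chain's single CQA).
#' @param imposed_pool Optional fixed pool value at `uo_id`.
#' @param uo_id Unit operation of the imposed pool.
#' @return List with `ds_mean_log`, `ds_sd_log`, `oos` (closed-form OOS
#'   probability against the CQA's limit) and `iac_closed_form(threshold)`,
#'   the imposed pool at `uo_id` that yields OOS exactly `threshold`.
#' @export
analytic_chain_oracle <- function(chain, cqa = NULL, imposed_pool = NULL,
                                  uo_id = NULL) {
  if (is.null(cqa)) cqa <- names(chain$cqas)[1]
  cq <- chain$cqas[[cqa]]
  r <- chain$ranges[[cqa]]
  sign <- if (cq$direction == "impurity") -1 else 1
  ms <- ss <- stats::setNames(numeric(diff(r) + 1L), as.character(r[1]:r[2]))
  for (k in r[1]:r[2]) {
    uo <- chain$uos[[as.character(k)]]
    if (cqa %in% uo$fallback) next  # pass-through: zero mean, zero variance
    model <- uo$models[[cqa]]
    if (!inherits(model, "manufacturing_sc")) {
      stop("analytic oracle requires manufacturing_sc models only; UO ", k,
           " has ", class(model)[1])
    }
    ms[as.character(k)] <- model$mean_log
    ss[as.character(k)] <- model$sd_log
  }
  downstream <- function(u) as.character(seq(u + 1L, r[2]))[u < r[2]]
  if (is.null(imposed_pool)) {
    ini <- chain$init[[cqa]]
    m <- ini$mean_log + sign * sum(ms)
    s <- sqrt(ini$sd_log^2 + sum(ss^2))
  } else {
    stopifnot(!is.null(uo_id), uo_id >= r[1], uo_id <= r[2])
    ds_ids <- downstream(uo_id)
    m <- log(imposed_pool) + sign * sum(ms[ds_ids])
    s <- sqrt(sum(ss[ds_ids]^2))
  }
  L <- primary_limit(cq)
  oos <- if (s == 0) {
    if (cq$side == "upper") as.numeric(m > log(L)) else as.numeric(m < log(L))
  } else if (cq$side == "upper") {
    stats::pnorm(log(L), m, s, lower.tail = FALSE)
  } else {
    stats::pnorm(log(L), m, s)
  }
  iac_closed_form <- function(threshold = 0.05, at_uo = uo_id) {
    stopifnot(!is.null(at_uo), at_uo >= r[1], at_uo <= r[2])
    ds_ids <- downstream(at_uo)
    S <- sum(ms[ds_ids]); sprime <- sqrt(sum(ss[ds_ids]^2))
    if (cq$side == "upper") {
      exp(log(L) + S - stats::qnorm(1 - threshold) * sprime)
    } else {
      exp(log(L) - S - stats::qnorm(threshold) * sprime)
    }
  }
  list(ds_mean_log = m, ds_sd_log = s, oos = oos,
       iac_closed_form = iac_closed_form)
}

# -- the default 9-UO synthetic process -------------------------------------

#' The default synthetic downstream process
#'
#' A 9-unit-operation chain with three CQAs: a host-cell-protein-like
#' impurity ("hcp", ng/mg, spanning ~4 decades, modelled UO 1–6 and flagged
#' `iac_equals_ds_spec` at the viral filtration UO 7 where all measurements
#' sit at the limit of quantification), an aggregate-like percent impurity
#' ("aggregates", UO 2–9) and a monomer-like percent purity ("monomer",
#' UO 2–9, lower DS limit 98%). Model types mix DoE, load-dependence (SC),
#' combined and manufacturing-distribution models across the chain. Effect
#' sizes are chosen so that process-parameter variation at 3% CV moves the
#' log performance by roughly half to one residual sd and the set-point OOS
#' probability stays in the 0.001–0.2 regime.
#'
#' @param seed Kept for interface symmetry; the construction is fully
#'   deterministic.
#' @return A [process_chain()] that is its own generating truth.
#' @export
make_default_process <- function(seed = 1L) {
  hcp <- quality_attribute("hcp", "impurity", "ng/mg", ds_spec = 10,
                           fit_scale = "log")
  agg <- quality_attribute("aggregates", "impurity", "%", ds_spec = 2)
  mon <- quality_attribute("monomer", "purity", "%", ds_spec = 98)

  pp <- list(
    temp1 = process_parameter("temperature", 20, design_range = c(16, 24)),
    cap_pH = process_parameter("load_pH", 7.2, design_range = c(6.8, 7.6)),
    cap_cond = process_parameter("load_cond", 5, design_range = c(4, 6)),
    stirrer = process_parameter("stirrer_speed", 200, design_range = c(150, 250)),
    aex_pH = process_parameter("eq_pH", 7.5, design_range = c(7, 8)),
    cex_cond = process_parameter("elu_cond", 12, design_range = c(10, 14)),
    cex_pH = process_parameter("elu_pH", 5.5, design_range = c(5, 6)),
    hic_pH = process_parameter("hic_pH", 6.8, design_range = c(6.4, 7.2)),
    hic_cond = process_parameter("hic_cond", 8, design_range = c(6, 10)),
    hic_temp = process_parameter("hic_temp", 22, design_range = c(18, 26)))

  cap_rng <- list(load_pH = c(6.8, 7.6), load_cond = c(4, 6))
  cex_rng <- list(elu_cond = c(10, 14), elu_pH = c(5, 6))
  hic_rng <- list(hic_pH = c(6.4, 7.2), hic_cond = c(6, 10),
                  hic_temp = c(18, 26))

  # typical specific load concentrations along the chain (set-point means)
  hcp_loads <- c(`1` = 2.5e5, `2` = 2.5e5 / exp(0.7), `3` = 2.5e5 / exp(5.7),
                 `4` = 2.5e5 / exp(6.0), `5` = 2.5e5 / exp(7.2),
                 `6` = 2.5e5 / exp(9.1))
  agg_load4 <- 5 / exp(0.30)
  agg_load5 <- 5 / exp(0.42)
  mon_load <- function(k) 97 * exp((k - 2) * 0.00218)

  hcp_capture_doe <- .make_doe_model(
    c(`(Intercept)` = 5.0, load_pH = 0.15), "load_pH",
    cap_rng["load_pH"], "ofat", resid_sd = 0.12,
    slc_doe = unname(hcp_loads["2"]), cqa = hcp)
  hcp_capture_sc <- .make_sc_model(
    a = 5.0 - 0.3 * log(hcp_loads["2"]), b = 0.3,
    slc_center = unname(hcp_loads["2"]), resid_sd = 0.10, cqa = hcp)

  mon_cex_doe <- .make_doe_model(
    c(`(Intercept)` = 0.00218, elu_pH = 0.0005), c("elu_cond", "elu_pH")[2],
    cex_rng["elu_pH"], "ofat", resid_sd = 8e-4,
    slc_doe = mon_load(6), cqa = mon, response_kind = "yield")
  mon_cex_sc <- .make_sc_model(
    a = 0.00218 + 0.005 * log(mon_load(6)), b = -0.005,
    slc_center = mon_load(6), resid_sd = 8e-4, spread_log = 0.004,
    cqa = mon, response_kind = "yield")

  uos <- list(
    unit_operation(1, "Harvest", pp["temp1"], models = list(
      hcp = manufacturing_sc(0.7, 0.15, cqa = hcp))),
    unit_operation(2, "Capture", pp[c("cap_pH", "cap_cond")], models = list(
      hcp = combined_model(hcp_capture_doe, hcp_capture_sc),
      aggregates = manufacturing_sc(0.25, 0.06, cqa = agg),
      monomer = manufacturing_sc(0.00218, 8e-4, cqa = mon,
                                 response_kind = "yield"))),
    unit_operation(3, "Virus inactivation", pp["stirrer"], models = list(
      hcp = manufacturing_sc(0.3, 0.08, cqa = hcp),
      aggregates = manufacturing_sc(0.05, 0.03, cqa = agg),
      monomer = manufacturing_sc(0.00218, 8e-4, cqa = mon,
                                 response_kind = "yield"))),
    unit_operation(4, "Depth filtration", models = list(
      hcp = .make_sc_model(1.2 - 0.25 * log(hcp_loads["4"]), 0.25,
                           unname(hcp_loads["4"]), 0.10, spread_log = 0.5,
                           cqa = hcp),
      aggregates = .make_sc_model(0.12 - 0.15 * log(agg_load4), 0.15,
                                  agg_load4, 0.05, spread_log = 0.25,
                                  cqa = agg),
      monomer = .make_sc_model(0.00218 + 0.005 * log(mon_load(4)), -0.005,
                               mon_load(4), 8e-4, spread_log = 0.005,
                               cqa = mon, response_kind = "yield"))),
    unit_operation(5, "AEX", pp["aex_pH"], models = list(
      hcp = .make_sc_model(1.9 - 0.25 * log(hcp_loads["5"]), 0.25,
                           unname(hcp_loads["5"]), 0.15, spread_log = 0.5,
                           cqa = hcp),
      aggregates = .make_sc_model(0.20 - 0.15 * log(agg_load5), 0.15,
                                  agg_load5, 0.06, spread_log = 0.26,
                                  cqa = agg),
      monomer = .make_sc_model(0.00218 + 0.005 * log(mon_load(5)), -0.005,
                               mon_load(5), 8e-4, spread_log = 0.005,
                               cqa = mon, response_kind = "yield"))),
    unit_operation(6, "CEX", pp[c("cex_cond", "cex_pH")], models = list(
      hcp = .make_doe_model(
        c(`(Intercept)` = 1.9, elu_cond = 0.35, elu_pH = -0.2),
        c("elu_cond", "elu_pH"), cex_rng, "grid5x3", resid_sd = 0.12,
        slc_doe = unname(hcp_loads["6"]), cqa = hcp),
      aggregates = .make_doe_model(
        c(`(Intercept)` = 0.35, elu_cond = 0.15),
        c("elu_cond", "elu_pH"), cex_rng, "grid5x3", resid_sd = 0.08,
        cqa = agg),
      monomer = combined_model(mon_cex_doe, mon_cex_sc))),
    unit_operation(7, "Viral filtration", models = list(
      aggregates = manufacturing_sc(0.10, 0.04, cqa = agg),
      monomer = manufacturing_sc(0.00218, 8e-4, cqa = mon,
                                 response_kind = "yield")),
      fallback = "hcp"),
    unit_operation(8, "HIC", pp[c("hic_pH", "hic_cond", "hic_temp")],
      models = list(
        aggregates = .make_doe_model(
          c(`(Intercept)` = 0.30, hic_pH = 0.15, hic_cond = -0.10,
            `hic_pH:hic_cond` = 0.08),
          c("hic_pH", "hic_cond", "hic_temp"), hic_rng, "ccf",
          resid_sd = 0.08, cqa = agg),
        monomer = .make_doe_model(
          c(`(Intercept)` = 0.00218, hic_pH = 6e-4),
          c("hic_pH", "hic_cond", "hic_temp"), hic_rng, "ccf",
          resid_sd = 8e-4, cqa = mon, response_kind = "yield"))),
    unit_operation(9, "UFDF", models = list(
      aggregates = manufacturing_sc(0.05, 0.03, cqa = agg),
      monomer = .make_sc_model(0.00218 + 0.005 * log(mon_load(9)), -0.005,
                               mon_load(9), 8e-4, spread_log = 0.006,
                               cqa = mon, response_kind = "yield"))))

  process_chain(uos, list(hcp, agg, mon),
                ranges = list(hcp = c(1L, 6L), aggregates = c(2L, 9L),
                              monomer = c(2L, 9L)),
                init = list(hcp = list(mean_log = log(2.5e5), sd_log = 0.25),
                            aggregates = list(mean_log = log(5), sd_log = 0.15),
                            monomer = list(mean_log = log(97), sd_log = 0.002)))
}

# -- dataset generators -----------------------------------------------------

#' Generate synthetic manufacturing runs
#'
#' Simulates `n` batches through the chain at set-point conditions (process
#' parameters sampled from their normal operating ranges) and records the
#' paired load/pool specific concentrations per unit operation and CQA at
#' manufacturing scale. Unit operations flagged `iac_equals_ds_spec` outside
#' a CQA's modelled sub-range yield rows at the limit of quantification
#' (flagged `TRUE` in the `*_loq` columns), emulating assay floors.
#'
#' @param chain A [process_chain()] (typically [make_default_process()]).
#' @param n Number of batches (default 10, a typical manufacturing history).
#' @param seed Seed for reproducibility.
#' @param loq Limit-of-quantification value used for flagged steps.
#' @return Data frame with columns `batch_id`, `uo_id`, `cqa`, `load_value`,
#'   `pool_value`, `scale`, `load_loq`, `pool_loq`.
#' @export
generate_manufacturing_runs <- function(chain, n = 10L, seed = 1L,
                                        loq = 0.1) {
  validate_chain(chain)
  cfg <- sim_config(n_runs = n, seed = seed)
  rows <- list()
  for (ci in seq_along(chain$cqas)) {
    cq_name <- names(chain$cqas)[ci]
    set.seed(derive_seed(seed, ci, 101L))
    res <- .sim_one_cqa(chain, cq_name, cfg, n)
    uo_ids <- as.integer(colnames(res$pools))
    for (j in seq_along(uo_ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        batch_id = sprintf("B%02d", seq_len(n)),
        uo_id = uo_ids[j], cqa = cq_name,
        load_value = res$loads[, j], pool_value = res$pools[, j],
        scale = "manufacturing", load_loq = FALSE, pool_loq = FALSE,
        stringsAsFactors = FALSE)
    }
    # LoQ rows for flagged UOs outside the modelled sub-range
    r <- chain$ranges[[cq_name]]
    for (uo in chain$uos) {
      if (cq_name %in% uo$fallback && (uo$id < r[1] || uo$id > r[2])) {
        rows[[length(rows) + 1L]] <- data.frame(
          batch_id = sprintf("B%02d", seq_len(n)),
          uo_id = uo$id, cqa = cq_name,
          load_value = loq, pool_value = loq,
          scale = "manufacturing", load_loq = TRUE, pool_loq = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$cqa, out$uo_id, out$batch_id), , drop = FALSE]
}

#' Generate a synthetic DoE dataset for one unit operation
#'
#' Builds the design matrix (in native units) of the requested experimental
#' design over the unit operation's process parameters and generates
#' responses from the chain's true DoE models plus lognormal noise at the
#' model's residual sd. All runs share the starting material, whose specific
#' load concentration is recorded in the `"slc"` attribute (and serialized
#' by [write_doe_csv()]).
#'
#' @param chain A [process_chain()] with DoE-type truth at `uo_id`.
#' @param uo_id Unit operation id.
#' @param design `"auto"` (by factor count), `"ofat"` (5 runs),
#'   `"grid5x3"` (11 runs) or `"ccf"` (17 runs with 3 center points).
#' @param n_center Center points for the `"ccf"` design (default 3).
#' @param seed Seed.
#' @return Data frame `run_id`, factor columns (native units), one
#'   `response_<cqa>` column per DoE-modelled CQA, `scale`; attributes
#'   `slc`, `factors`, `design`, `uo_id`.
#' @export
generate_doe <- function(chain, uo_id, design = c("auto", "ofat", "grid5x3",
                                                  "ccf"),
                         n_center = 3L, seed = 1L) {
  design <- match.arg(design)
  uo <- chain$uos[[as.character(uo_id)]]
  if (is.null(uo)) stop("no unit operation with id ", uo_id)
  doe_cqas <- names(uo$models)[vapply(uo$models, inherits, logical(1),
                                      what = c("doe_model", "combined_model"))]
  if (!length(doe_cqas)) stop("UO ", uo_id, " has no DoE-type model")
  truths <- lapply(uo$models[doe_cqas],
                   function(m) if (inherits(m, "combined_model")) m$doe else m)
  factors <- unique(unlist(lapply(truths, `[[`, "factors")))
  ranges <- truths[[1]]$design_ranges[factors]
  if (design == "auto") {
    design <- c("ofat", "grid5x3", "ccf")[min(length(factors), 3L)]
  }
  Zc <- .coded_design(design, length(factors), n_center)
  colnames(Zc) <- factors
  native <- vapply(factors, function(f) unscale_factor(Zc[, f], ranges[[f]]),
                   numeric(nrow(Zc)))
  native <- matrix(native, nrow = nrow(Zc),
                   dimnames = list(NULL, factors))
  out <- data.frame(run_id = sprintf("R%02d", seq_len(nrow(Zc))), native,
                    stringsAsFactors = FALSE)
  set.seed(derive_seed(seed, uo_id, 202L))
  slc <- stats::setNames(numeric(length(doe_cqas)), doe_cqas)
  for (cq in doe_cqas) {
    tr <- truths[[cq]]
    # design may differ from the truth's: evaluate the truth at these points
    X0 <- .doe_design_rows(tr, native[, tr$factors, drop = FALSE])
    mu <- drop(X0 %*% tr$coef)
    out[[paste0("response_", cq)]] <- exp(mu + stats::rnorm(nrow(Zc), 0,
                                                            tr$residual_sd))
    slc[cq] <- if (is.finite(tr$slc_doe)) tr$slc_doe else NA_real_
  }
  out$scale <- "small"
  attr(out, "slc") <- slc
  attr(out, "factors") <- factors
  attr(out, "design") <- design
  attr(out, "uo_id") <- as.integer(uo_id)
  out
}
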