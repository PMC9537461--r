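# Model fitting for unit-operation performance indicators.
#
# Three model variants describe one UO x CQA combination:
#   * doe_model         — log(performance) ~ coded process parameters (OLS,
#                         best-subset selection under strong heredity)
#   * sc_model          — log(performance) ~ log(specific load concentration)
#   * manufacturing_sc  — lognormal distribution fitted to manufacturing
#                         performance values (no covariates)
# plus combined_model(doe, sc), which corrects the DoE prediction for the
# difference between the simulation load and the DoE starting material.

# Fast OLS with the pieces needed for predictive sampling. Returns NULL on a
# singular design or non-positive error dof.
.ols <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  dof <- n - p
  if (dof < 1L) return(NULL)
  qrx <- qr(X)
  if (qrx$rank < p) return(NULL)
  coef <- qr.coef(qrx, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  s2 <- sum(res^2) / dof
  R <- qr.R(qrx)
  XtXinv <- chol2inv(R)
  piv <- qrx$pivot
  XtXinv[piv, piv] <- XtXinv
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(XtXinv), 0) * s2)
  tstat <- coef / se
  pval <- 2 * stats::pt(-abs(tstat), dof)
  pval[!is.finite(tstat)] <- 0   # zero-noise exact fit: treat as significant
  pval[is.nan(pval)] <- 1
  list(coef = coef, XtXinv = XtXinv, residual_sd = sqrt(s2), dof = dof,
       p_values = pval, residuals = res, fitted = fitted)
}

# Column for one model term from the coded factor matrix Z (columns = factors).
.term_column <- function(term, Z) {
  if (grepl(":", term, fixed = TRUE)) {
    f <- strsplit(term, ":", fixed = TRUE)[[1]]
    Z[, f[1]] * Z[, f[2]]
  } else if (grepl("^", term, fixed = TRUE)) {
    f <- sub("\\^2$", "", term)
    Z[, f]^2
  } else {
    Z[, term]
  }
}

.term_parents <- function(term) {
  if (grepl(":", term, fixed = TRUE)) strsplit(term, ":", fixed = TRUE)[[1]]
  else if (grepl("^", term, fixed = TRUE)) sub("\\^2$", "", term)
  else character(0)
}

# All term subsets obeying strong heredity: an interaction requires both main
# effects, a quadratic its main effect. Designs have <= 3 factors so full
# enumeration is cheap (95 subsets for 3 factors with all 2FIs + quadratics).
.heredity_subsets <- function(mains, inters, quads) {
  out <- list()
  nm <- length(mains)
  for (mask in 0:(2^nm - 1L)) {
    ms <- mains[bitwAnd(mask, 2^(seq_len(nm) - 1L)) > 0L]
    ok_int <- inters[vapply(inters, function(t) all(.term_parents(t) %in% ms),
                            logical(1))]
    ok_quad <- quads[vapply(quads, function(t) .term_parents(t) %in% ms,
                            logical(1))]
    extra <- c(ok_int, ok_quad)
    ne <- length(extra)
    for (emask in 0:(2^ne - 1L)) {
      es <- extra[bitwAnd(emask, 2^(seq_len(ne) - 1L)) > 0L]
      out[[length(out) + 1L]] <- c(ms, es)
    }
  }
  unique(out)
}

#' Fit a DoE model for a unit operation's performance
#'
#' Ordinary least squares of the log-transformed performance indicator
#' (specific clearance or yield) on process-parameter factors coded to
#' \[-1, 1\]. Candidate terms are limited by the resolution of the design
#' (OFAT: main effects only; the 11-run 5x3 grid: mains + quadratics;
#' face-centered central composite: mains + two-factor interactions +
#' quadratics). A best-subset search over all strong-heredity-respecting
#' term sets keeps every subset whose non-forced terms all have partial-t
#' p-values below `p_threshold`, then selects the largest such subset
#' (ties broken by smaller residual sd) so that potentially critical process
#' parameters are not overlooked. Main effects forced in by heredity are
#' exempt from the threshold. Scale is included as a fixed-effect indicator
#' when both scales are present; the response is neither scaled nor centered.
#'
#' @param data Data frame with one row per experimental run: factor columns in
#'   native units, a positive response column, optionally a `scale` column
#'   with levels `"small"` / `"manufacturing"`.
#' @param factors Character vector of factor column names.
#' @param response Name of the response column (positive values; the model is
#'   fitted on its natural log).
#' @param design_ranges Named list of `c(low, high)` per factor for the
#'   \[-1, 1\] coding; defaults to each factor's observed range.
#' @param design Design resolution: `"auto"` (by factor count), `"ofat"`,
#'   `"grid5x3"` or `"ccf"`.
#' @param p_threshold Partial-t p-value threshold for term selection
#'   (default 0.1, deliberately looser than 0.05).
#' @param cqa Optional [quality_attribute()] the response belongs to.
#' @param response_kind `"specific_clearance"` or `"yield"`.
#' @param slc_doe Specific load concentration of the DoE starting material
#'   (all runs of a DoE share it); required when the model is later combined
#'   with a load-dependence model.
#' @return An object of class `"doe_model"`.
#' @export
fit_doe_model <- function(data, factors, response,
                          design_ranges = NULL,
                          design = c("auto", "ofat", "grid5x3", "ccf"),
                          p_threshold = 0.1,
                          cqa = NULL,
                          response_kind = c("specific_clearance", "yield"),
                          slc_doe = NA_real_) {
  design <- match.arg(design)
  response_kind <- match.arg(response_kind)
  stopifnot(is.data.frame(data), all(factors %in% names(data)),
            response %in% names(data))
  yraw <- data[[response]]
  check_positive(yraw, paste0("response '", response, "'"))
  y <- log(yraw)
  n <- nrow(data)

  if (is.null(design_ranges)) {
    design_ranges <- lapply(data[factors], range)
    names(design_ranges) <- factors
  }
  Z <- vapply(factors, function(f) scale_factor(data[[f]], design_ranges[[f]]),
              numeric(n))
  Z <- matrix(Z, nrow = n, dimnames = list(NULL, factors))

  if (design == "auto") {
    design <- c("ofat", "grid5x3", "ccf")[min(length(factors), 3L)]
  }
  mains <- factors
  inters <- if (design == "ccf" && length(factors) >= 2L) {
    cmb <- utils::combn(factors, 2L)
    apply(cmb, 2L, paste, collapse = ":")
  } else character(0)
  quads <- if (design %in% c("ccf", "grid5x3")) paste0(factors, "^2")
           else character(0)

  has_scale <- "scale" %in% names(data) &&
    length(unique(data$scale)) > 1L
  scale_col <- if (has_scale) as.numeric(data$scale == "manufacturing")

  subsets <- .heredity_subsets(mains, as.list(inters), as.list(quads))
  best <- NULL; best_terms <- character(0)
  n_singular <- 0L
  for (terms in subsets) {
    terms <- unlist(terms)
    Xt <- if (length(terms)) {
      vapply(terms, .term_column, numeric(n), Z = Z)
    } else NULL
    X <- cbind(`(Intercept)` = rep(1, n), scale = scale_col, Xt)
    if (length(terms)) {
      colnames(X)[(ncol(X) - length(terms) + 1L):ncol(X)] <- terms
    }
    fit <- .ols(X, y)
    if (is.null(fit)) { n_singular <- n_singular + 1L; next }
    # mains forced in by a selected child are exempt from the threshold
    children <- terms[vapply(terms, function(t) length(.term_parents(t)) > 0,
                             logical(1))]
    forced <- unique(unlist(lapply(children, .term_parents)))
    testable <- setdiff(terms, forced)
    if (length(testable) && any(fit$p_values[testable] >= p_threshold)) next
    better <- is.null(best) ||
      length(terms) > length(best_terms) ||
      (length(terms) == length(best_terms) &&
         fit$residual_sd < best$residual_sd)
    if (better) { best <- fit; best_terms <- terms }
  }
  if (is.null(best)) {
    warning("no admissible subset could be fitted; returning intercept-only model")
    X <- cbind(`(Intercept)` = rep(1, n))
    best <- .ols(X, y)
    if (is.null(best)) stop("cannot fit even an intercept-only model (n too small)")
    best_terms <- character(0)
  }

  structure(list(
    cqa = cqa, response_kind = response_kind,
    terms = best_terms, coef = best$coef, XtXinv = best$XtXinv,
    residual_sd = best$residual_sd, dof = best$dof,
    p_values = best$p_values,
    factors = factors, design_ranges = design_ranges, design = design,
    has_scale = has_scale, slc_doe = slc_doe,
    residuals = best$residuals, fitted = best$fitted, n = n,
    selection = list(n_subsets = length(subsets), n_singular = n_singular,
                     p_threshold = p_threshold)
  ), class = "doe_model")
}

#' @export
print.doe_model <- function(x, ...) {
  cat(sprintf("<doe_model> log(%s) ~ %s\n", x$response_kind,
              paste(c("1", if (x$has_scale) "scale", x$terms), collapse = " + ")))
  cat(sprintf("  n = %d, residual sd = %.4g, dof = %d\n", x$n, x$residual_sd, x$dof))
  invisible(x)
}

#' Fit a load-dependence (SC) model from manufacturing data
#'
#' OLS of the log performance indicator on the log specific load
#' concentration: `log(response) = a + b * log(SLC)`. Performance is
#' multiplicative and strictly positive, so the log-log form is the minimal
#' one consistent with log-transformed responses. The observed load range is
#' stored: predictions outside it are clamped to the boundary (no
#' extrapolation of clearances).
#'
#' @param data Data frame with positive `load_value` and `pool_value` columns
#'   (paired records of one unit operation).
#' @param cqa Optional [quality_attribute()].
#' @param response_kind `"specific_clearance"` (impurities) or `"yield"`.
#' @return An object of class `"sc_model"`; its `significant` field is FALSE
#'   when the slope's p-value is >= 0.1, in which case callers should prefer
#'   [fit_manufacturing_sc()].
#' @export
fit_sc_model <- function(data, cqa = NULL,
                         response_kind = c("specific_clearance", "yield")) {
  response_kind <- match.arg(response_kind)
  stopifnot(is.data.frame(data),
            all(c("load_value", "pool_value") %in% names(data)))
  if (nrow(data) < 4L) stop("fit_sc_model needs >= 4 records, got ", nrow(data))
  load <- data$load_value; pool <- data$pool_value
  resp <- if (response_kind == "specific_clearance") {
    compute_specific_clearance(load, pool)
  } else {
    compute_yield(load, pool)
  }
  y <- log(resp)
  x <- log(load)
  X <- cbind(`(Intercept)` = 1, log_slc = x)
  fit <- .ols(X, y)
  if (is.null(fit)) stop("singular design: all load values identical?")
  p_slope <- unname(fit$p_values["log_slc"])
  structure(list(
    cqa = cqa, response_kind = response_kind,
    coef = fit$coef, XtXinv = fit$XtXinv,
    residual_sd = fit$residual_sd, dof = fit$dof,
    p_slope = p_slope, significant = is.finite(p_slope) && p_slope < 0.1,
    train_range = range(load),
    residuals = fit$residuals, fitted = fit$fitted, n = nrow(data)
  ), class = "sc_model")
}

#' @export
print.sc_model <- function(x, ...) {
  cat(sprintf("<sc_model> log(%s) = %.4g %+.4g * log(SLC)  [slope p = %.3g%s]\n",
              x$response_kind, x$coef[1], x$coef[2], x$p_slope,
              if (!x$significant) ", not significant" else ""))
  cat(sprintf("  n = %d, residual sd = %.4g, load range [%.4g, %.4g]\n",
              x$n, x$residual_sd, x$train_range[1], x$train_range[2]))
  invisible(x)
}

#' Fit a lognormal clearance/yield distribution to manufacturing data
#'
#' When neither a DoE nor a load-dependence model is available, the
#' performance of a unit operation is described by a normal distribution
#' fitted to the log performance values observed in manufacturing.
#'
#' @param values Positive performance values (specific clearances or yields),
#'   at least two.
#' @param cqa Optional [quality_attribute()].
#' @param response_kind `"specific_clearance"` or `"yield"`.
#' @return An object of class `"manufacturing_sc"` with fields `mean_log`,
#'   `sd_log` (sample sd) and `n`.
#' @export
fit_manufacturing_sc <- function(values, cqa = NULL,
                                 response_kind = c("specific_clearance",
                                                   "yield")) {
  response_kind <- match.arg(response_kind)
  if (length(values) < 2L) {
    stop("fit_manufacturing_sc needs n >= 2 values, got ", length(values))
  }
  check_positive(values, "performance values")
  lv <- log(values)
  structure(list(cqa = cqa, response_kind = response_kind,
                 mean_log = mean(lv), sd_log = stats::sd(lv),
                 n = length(values)),
            class = "manufacturing_sc")
}

#' @export
print.manufacturing_sc <- function(x, ...) {
  cat(sprintf("<manufacturing_sc> log(%s) ~ N(%.4g, %.4g), n = %d\n",
              x$response_kind, x$mean_log, x$sd_log, x$n))
  invisible(x)
}

#' Construct a manufacturing-SC distribution from known parameters
#'
#' Used by the synthetic-process generator and for tests where the lognormal
#' parameters are ground truth rather than estimates.
#'
#' @param mean_log,sd_log Log-scale mean and sd (`sd_log >= 0`).
#' @param n Nominal sample size (>= 2).
#' @inheritParams fit_manufacturing_sc
#' @return A `"manufacturing_sc"` object.
#' @export
manufacturing_sc <- function(mean_log, sd_log, n = 10L, cqa = NULL,
                             response_kind = c("specific_clearance", "yield")) {
  response_kind <- match.arg(response_kind)
  stopifnot(is.finite(mean_log), is.finite(sd_log), sd_log >= 0, n >= 2)
  structure(list(cqa = cqa, response_kind = response_kind,
                 mean_log = mean_log, sd_log = sd_log, n = as.integer(n)),
            class = "manufacturing_sc")
}

#' Combine a DoE model with a load-dependence model
#'
#' When both model types exist for one unit operation, the DoE prediction
#' (valid at the concentration of the DoE starting material) is corrected by
#' the ratio of load-model predictions at the simulation input concentration
#' versus at the DoE starting concentration:
#' `SC = SC_doe(PP) * SC_load(SLC) / SC_load(SLC_doe)`.
#' The correction factor is deterministic given the load (mean predictions in
#' numerator and denominator); the DoE draw carries the stochasticity, so the
#' combined prediction at `slc = slc_doe` is identical to the DoE-only
#' prediction draw by draw.
#'
#' @param doe A `"doe_model"` with a finite `slc_doe`.
#' @param sc An `"sc_model"` for the same CQA and response kind.
#' @return An object of class `"combined_model"`.
#' @export
combined_model <- function(doe, sc) {
  stopifnot(inherits(doe, "doe_model"), inherits(sc, "sc_model"))
  if (!is.finite(doe$slc_doe) || doe$slc_doe <= 0) {
    stop("combined_model requires the DoE starting-material SLC (slc_doe)")
  }
  if (!identical(doe$response_kind, sc$response_kind)) {
    stop("DoE and SC models describe different response kinds")
  }
  structure(list(doe = doe, sc = sc, cqa = doe$cqa,
                 response_kind = doe$response_kind),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat("<combined_model> DoE model with deterministic load correction\n")
  print(x$doe); print(x$sc)
  invisible(x)
}

#' Residual diagnostics for a fitted performance model
#'
#' Advisory checks of the OLS assumptions: normality of residuals
#' (Shapiro-Wilk), constant variance (correlation of absolute residuals with
#' fitted values) and run-order independence (lag-1 autocorrelation). Flags
#' are raised, never hard failures — small DoEs have limited diagnostic
#' power and the analyst decides.
#'
#' @param model A `"doe_model"` or `"sc_model"` (stores residuals and fitted
#'   values).
#' @return An object of class `"ipm_diagnostics"`: a list with per-check
#'   statistics, p-values where defined, and logical flags.
#' @export
residual_diagnostics <- function(model) {
  stopifnot(!is.null(model$residuals), !is.null(model$fitted))
  r <- model$residuals; f <- model$fitted
  n <- length(r)
  degenerate <- all(abs(r) < 1e-12)
  out <- list(n = n, degenerate = degenerate)

  if (degenerate || n < 3L) {
    out$normality <- list(stat = NA_real_, p = NA_real_, flag = FALSE)
    out$heteroscedasticity <- list(cor = NA_real_, flag = FALSE)
    out$independence <- list(lag1 = NA_real_, flag = FALSE)
  } else {
    sw <- stats::shapiro.test(r)
    out$normality <- list(stat = unname(sw$statistic), p = sw$p.value,
                          flag = sw$p.value < 0.05)
    hc <- if (stats::sd(f) > 0) stats::cor(abs(r), f) else 0
    # |cor| beyond ~2/sqrt(n) indicates a variance trend with the mean
    out$heteroscedasticity <- list(cor = hc, flag = abs(hc) > 2 / sqrt(n))
    l1 <- stats::cor(r[-1], r[-n])
    out$independence <- list(lag1 = l1, flag = abs(l1) > 2 / sqrt(n))
  }
  out$any_flag <- isTRUE(out$normality$flag) ||
    isTRUE(out$heteroscedasticity$flag) || isTRUE(out$independence$flag)
  structure(out, class = "ipm_diagnostics")
}

#' @export
print.ipm_diagnostics <- function(x, ...) {
  cat("<ipm_diagnostics>",
      if (x$degenerate) "exact fit (degenerate residuals)\n" else "\n")
  if (!x$degenerate) {
    cat(sprintf("  normality: W = %.3f, p = %.3g%s\n", x$normality$stat,
                x$normality$p, if (x$normality$flag) "  [FLAG]" else ""))
    cat(sprintf("  |resid| vs fitted cor = %.3f%s\n", x$heteroscedasticity$cor,
                if (x$heteroscedasticity$flag) "  [FLAG]" else ""))
    cat(sprintf("  lag-1 autocorrelation = %.3f%s\n", x$independence$lag1,
                if (x$independence$flag) "  [FLAG]" else ""))
  }
  invisible(x)
}
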