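# Stochastic performance prediction.
#
# One Monte-Carlo draw of a unit operation's performance indicator is the
# model's mean log-prediction plus a random prediction error, exponentiated.
# For OLS models the error is t-distributed with the model's error dof and
# scaled by the prediction standard error, which includes both parameter
# uncertainty (via the stored (X'X)^-1) and residual variance — i.e. a draw
# from the predictive distribution whose central 95% region is the usual 95%
# prediction interval. The literal reading "drawn from the 95% prediction
# interval" is available as sampling = "truncated_95" (the t error truncated
# at the interval bounds).

.t_draws <- function(n, dof, sampling, pi_level) {
  if (sampling == "predictive_t") {
    stats::rt(n, df = dof)
  } else {
    tq <- stats::qt(1 - (1 - pi_level) / 2, df = dof)
    u <- stats::runif(n, stats::pt(-tq, dof), stats::pt(tq, dof))
    stats::qt(u, df = dof)
  }
}

# Mean log-prediction of an sc_model at (already clamped) native loads.
.sc_mean_log <- function(model, slc) {
  unname(model$coef[1] + model$coef[2] * log(slc))
}

.clamp_slc <- function(model, slc) {
  lo <- model$train_range[1]; hi <- model$train_range[2]
  clamped <- slc < lo | slc > hi
  list(slc = pmin(pmax(slc, lo), hi), n_clamped = sum(clamped))
}

# Build the prediction design row(s) of a doe_model from native PP values.
# pp: matrix n x length(factors) with factor names as columns. Predictions
# are made at the manufacturing level of the scale indicator.
.doe_design_rows <- function(model, pp) {
  missing <- setdiff(model$factors, colnames(pp))
  if (length(missing)) {
    stop("missing process parameter value(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(pp)
  Z <- vapply(model$factors,
              function(f) scale_factor(pp[, f], model$design_ranges[[f]]),
              numeric(n))
  Z <- matrix(Z, nrow = n, dimnames = list(NULL, model$factors))
  Xt <- if (length(model$terms)) {
    m <- vapply(model$terms, .term_column, numeric(n), Z = Z)
    matrix(m, nrow = n, dimnames = list(NULL, model$terms))
  } else NULL
  X <- cbind(`(Intercept)` = rep(1, n),
             if (model$has_scale) cbind(scale = rep(1, n)), Xt)
  X[, names(model$coef), drop = FALSE]
}

# se of a new prediction (includes residual variance).
.pred_se <- function(X0, XtXinv, residual_sd) {
  residual_sd * sqrt(1 + rowSums((X0 %*% XtXinv) * X0))
}

# Vectorized predictive draws; returns n positive values with attribute
# "n_clamped" (count of load values clamped to the SC training range).
.draw_perf <- function(model, pp = NULL, slc = NULL, n = 1L,
                       sampling = "predictive_t", pi_level = 0.95) {
  UseMethod(".draw_perf")
}

#' @export
.draw_perf.manufacturing_sc <- function(model, pp = NULL, slc = NULL, n = 1L,
                                        sampling = "predictive_t",
                                        pi_level = 0.95) {
  out <- exp(stats::rnorm(n, model$mean_log, model$sd_log))
  attr(out, "n_clamped") <- 0L
  out
}

#' @export
.draw_perf.sc_model <- function(model, pp = NULL, slc = NULL, n = 1L,
                                sampling = "predictive_t", pi_level = 0.95) {
  if (is.null(slc)) stop("sc_model prediction needs the specific load concentration")
  check_positive(slc, "slc")
  slc <- rep_len(slc, n)
  cl <- .clamp_slc(model, slc)
  X0 <- cbind(`(Intercept)` = rep(1, n), log_slc = log(cl$slc))
  mu <- drop(X0 %*% model$coef)
  se <- .pred_se(X0, model$XtXinv, model$residual_sd)
  out <- exp(mu + .t_draws(n, model$dof, sampling, pi_level) * se)
  attr(out, "n_clamped") <- cl$n_clamped
  out
}

#' @export
.draw_perf.doe_model <- function(model, pp = NULL, slc = NULL, n = 1L,
                                 sampling = "predictive_t", pi_level = 0.95) {
  if (is.null(pp)) {
    if (length(model$factors)) {
      stop("doe_model prediction needs process-parameter values")
    }
    pp <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  if (is.null(dim(pp))) pp <- matrix(pp, nrow = n, ncol = length(pp),
                                     byrow = TRUE, dimnames = list(NULL, names(pp)))
  X0 <- .doe_design_rows(model, pp)
  mu <- drop(X0 %*% model$coef)
  se <- .pred_se(X0, model$XtXinv, model$residual_sd)
  out <- exp(mu + .t_draws(n, model$dof, sampling, pi_level) * se)
  attr(out, "n_clamped") <- 0L
  out
}

#' @export
.draw_perf.combined_model <- function(model, pp = NULL, slc = NULL, n = 1L,
                                      sampling = "predictive_t",
                                      pi_level = 0.95) {
  if (is.null(slc)) stop("combined_model prediction needs the load concentration")
  base <- .draw_perf(model$doe, pp = pp, slc = NULL, n = n,
                     sampling = sampling, pi_level = pi_level)
  slc <- rep_len(slc, n)
  cl <- .clamp_slc(model$sc, slc)
  ref <- .clamp_slc(model$sc, model$doe$slc_doe)$slc
  corr <- exp(.sc_mean_log(model$sc, cl$slc) - .sc_mean_log(model$sc, ref))
  out <- as.numeric(base) * corr
  attr(out, "n_clamped") <- cl$n_clamped
  out
}

#' Draw stochastic performance predictions from a fitted model
#'
#' One (or `n`) random draw(s) of the performance indicator (specific
#' clearance or yield) on the natural scale. For DoE and load-dependence
#' models the draw is mean log-prediction plus a t-distributed prediction
#' error (parameter + residual variance); for a manufacturing distribution
#' it is a plain lognormal draw. Combined models apply the deterministic
#' load-correction factor to the DoE draw; at `slc` equal to the DoE
#' starting concentration the correction is exactly 1. Loads outside an SC
#' model's training range are clamped to the boundary (clearance assumed
#' constant beyond the observed range — no extrapolation); the number of
#' clamped draws is returned in the `"n_clamped"` attribute.
#'
#' @param model A `"doe_model"`, `"sc_model"`, `"manufacturing_sc"` or
#'   `"combined_model"`.
#' @param pp_values Named numeric vector (or `n`-row matrix) of process-
#'   parameter values in native units; required for DoE-based models.
#' @param slc Positive specific load concentration(s); required for SC-based
#'   models.
#' @param n Number of draws.
#' @param sampling `"predictive_t"` (default) or `"truncated_95"` (error
#'   truncated at the `pi_level` prediction-interval bounds).
#' @param pi_level Prediction-interval level used by `"truncated_95"`.
#' @return Numeric vector of `n` positive draws, attribute `"n_clamped"`.
#' @export
#' @examples
#' m <- manufacturing_sc(mean_log = log(10), sd_log = 0)
#' predict_performance(m, n = 3) # deterministic: 10 10 10
predict_performance <- function(model, pp_values = NULL, slc = NULL, n = 1L,
                                sampling = c("predictive_t", "truncated_95"),
                                pi_level = 0.95) {
  sampling <- match.arg(sampling)
  .draw_perf(model, pp = pp_values, slc = slc, n = n,
             sampling = sampling, pi_level = pi_level)
}
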