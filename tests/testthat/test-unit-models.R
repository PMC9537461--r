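# Performance indicators, factor scaling and the three model variants.

test_that("specific clearance and yield are exact reciprocals", {
  expect_equal(compute_specific_clearance(10, 1), 10)
  expect_equal(compute_specific_clearance(2.5e5, 1.3e3), 2.5e5 / 1.3e3)
  expect_equal(compute_yield(100, 95), 0.95)
  set.seed(1)
  for (i in 1:50) {
    a <- exp(rnorm(1, 0, 3)); b <- exp(rnorm(1, 0, 3))
    expect_equal(compute_yield(a, b) * compute_specific_clearance(a, b), 1)
    expect_equal(compute_specific_clearance(a, a), 1)
  }
  expect_error(compute_specific_clearance(-1, 2), "positive")
  expect_error(compute_yield(1, 0), "positive")
  expect_error(compute_specific_clearance(NA, 2), "positive")
})

test_that("factor scaling is affine, order-preserving and invertible", {
  expect_equal(scale_factor(5, c(2, 8)), 0)
  expect_equal(scale_factor(8, c(2, 8)), 1)
  expect_equal(scale_factor(2, c(2, 8)), -1)
  expect_gt(scale_factor(9, c(2, 8)), 1)   # extrapolation maps outside
  set.seed(2)
  for (i in 1:50) {
    rng <- sort(rnorm(2, 0, 10))
    v <- runif(5, rng[1] - 5, rng[2] + 5)
    expect_equal(unscale_factor(scale_factor(v, rng), rng), v,
                 tolerance = 1e-12)
  }
  expect_error(scale_factor(1, c(3, 3)), "degenerate")
})

test_that("manufacturing-SC distribution fit matches log moments", {
  m <- fit_manufacturing_sc(rep(7, 5))
  expect_equal(m$mean_log, log(7))
  expect_equal(m$sd_log, 0)
  set.seed(3)
  m2 <- fit_manufacturing_sc(exp(rnorm(1e4, 2, 0.3)))
  expect_lt(abs(m2$mean_log - 2), 0.01)           # large-sample oracle
  expect_lt(abs(m2$sd_log - 0.3), 0.01)
  expect_error(fit_manufacturing_sc(5), "n >= 2")
  expect_error(fit_manufacturing_sc(c(1, -1)), "positive")
})

test_that("SC model recovers a known load dependence", {
  set.seed(4)
  slc <- exp(rnorm(10, 5, 0.5))
  sc <- exp(1 + 0.4 * log(slc) + rnorm(10, 0, 0.1))
  d <- data.frame(load_value = slc, pool_value = slc / sc)
  m <- fit_sc_model(d)
  se_slope <- m$residual_sd * sqrt(m$XtXinv["log_slc", "log_slc"])
  expect_lt(abs(m$coef["log_slc"] - 0.4), 3 * se_slope)
  expect_equal(m$train_range, range(slc))

  # exact line through two distinct load values: zero residuals
  slc2 <- rep(c(10, 100), each = 2)
  sc2 <- exp(0.5 + 0.2 * log(slc2))
  d2 <- data.frame(load_value = slc2, pool_value = slc2 / sc2)
  m2 <- fit_sc_model(d2)
  expect_equal(max(abs(m2$residuals)), 0, tolerance = 1e-12)
  expect_equal(unname(m2$coef), c(0.5, 0.2), tolerance = 1e-10)

  # constant response, zero noise: slope 0, intercept log(SC)
  d3 <- data.frame(load_value = c(10, 20, 40, 80),
                   pool_value = c(10, 20, 40, 80) / 6)
  m3 <- fit_sc_model(d3)
  expect_equal(unname(m3$coef["log_slc"]), 0, tolerance = 1e-12)
  expect_equal(unname(m3$coef["(Intercept)"]), log(6), tolerance = 1e-12)
  expect_false(m3$significant)

  expect_error(fit_sc_model(d3[1:3, ]), ">= 4")
})

test_that("best-subset DoE selection keeps the null model under pure noise", {
  # frozen simulation oracle, seed list 1..200: 176 of 200 OFAT fits on a
  # zero-slope response select the intercept-only model (expected rate 0.9
  # at the 0.1 partial-t threshold)
  sel <- vapply(1:200, function(s) {
    set.seed(s)
    d <- data.frame(x = c(-1, -0.5, 0, 0.5, 1), y = exp(rnorm(5, 2, 0.05)))
    m <- fit_doe_model(d, "x", "y", list(x = c(-1, 1)), design = "ofat")
    length(m$terms) == 0L
  }, logical(1))
  expect_identical(sum(sel), 176L)
})

test_that("strong heredity forces parent main effects into the model", {
  d <- make_ccf_truth_data(seed = 42)
  m <- fit_doe_model(d, c("x1", "x2", "x3"), "y", ccf_ranges, design = "ccf")
  expect_true(all(c("x1", "x2", "x1:x2") %in% m$terms))
  # x2's true main effect is 0, so it is forced, not significant
  expect_gte(m$p_values[["x2"]], 0)
  # structural heredity on a batch of refits
  for (s in 1:20) {
    d <- make_ccf_truth_data(seed = 100 + s)
    m <- fit_doe_model(d, c("x1", "x2", "x3"), "y", ccf_ranges,
                       design = "ccf")
    for (t in m$terms) {
      expect_true(all(ipmiac:::.term_parents(t) %in% m$terms),
                  info = paste("seed", s, "term", t))
    }
  }
})

test_that("scale enters as a fixed effect only when both scales are present", {
  set.seed(7)
  d <- data.frame(x = rep(c(-1, 0, 1), 4),
                  scale = rep(c("small", "manufacturing"), each = 6))
  d$y <- exp(1 + 0.5 * d$x + 0.3 * (d$scale == "manufacturing") +
               rnorm(12, 0, 0.05))
  m <- fit_doe_model(d, "x", "y", list(x = c(-1, 1)), design = "ofat")
  expect_true(m$has_scale)
  expect_true("scale" %in% names(m$coef))
  d_small <- d[d$scale == "small", ]
  m2 <- fit_doe_model(d_small, "x", "y", list(x = c(-1, 1)), design = "ofat")
  expect_false(m2$has_scale)
})

test_that("deterministic predictions and the combined-model identity", {
  m <- manufacturing_sc(log(10), 0)
  expect_equal(predict_performance(m, n = 5), rep(10, 5),
               ignore_attr = TRUE)

  # combined prediction at slc = slc_doe equals the DoE-only draw exactly
  doe <- ipmiac:::.make_doe_model(c(`(Intercept)` = 2, x = 0.4), "x",
                                  list(x = c(-1, 1)), "ofat",
                                  resid_sd = 0.1, slc_doe = 50)
  sc <- ipmiac:::.make_sc_model(0.5, 0.3, 50, 0.1)
  cm <- combined_model(doe, sc)
  pp <- c(x = 0.3)
  set.seed(11); a <- predict_performance(doe, pp, n = 100)
  set.seed(11); b <- predict_performance(cm, pp, slc = 50, n = 100)
  expect_identical(as.numeric(a), as.numeric(b))
  # away from slc_doe the deterministic correction factor applies
  set.seed(11); c1 <- predict_performance(cm, pp, slc = 70, n = 100)
  corr <- exp(0.3 * (log(70) - log(50)))
  expect_equal(as.numeric(c1), as.numeric(a) * corr, tolerance = 1e-12)
})

test_that("SC predictions are clamped outside the training load range", {
  sc <- ipmiac:::.make_sc_model(0.5, 0.3, 50, 0.1, spread_log = 0.2)
  hi <- sc$train_range[2]
  set.seed(12); a <- predict_performance(sc, slc = hi * 4, n = 1e4)
  set.seed(12); b <- predict_performance(sc, slc = hi, n = 1e4)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_identical(attr(a, "n_clamped"), 10000L)
  expect_identical(attr(b, "n_clamped"), 0L)
  set.seed(12); lo <- predict_performance(sc, slc = sc$train_range[1] / 3,
                                          n = 100)
  expect_identical(attr(lo, "n_clamped"), 100L)
})

test_that("truncated-95 sampling stays inside the prediction interval", {
  sc <- ipmiac:::.make_sc_model(0.5, 0.3, 50, 0.2, spread_log = 0.2)
  set.seed(13)
  dr <- log(predict_performance(sc, slc = 50, n = 5e3,
                                sampling = "truncated_95"))
  mu <- 0.5 + 0.3 * log(50)
  x0 <- c(1, log(50))
  se <- 0.2 * sqrt(1 + drop(t(x0) %*% sc$XtXinv %*% x0))
  bound <- qt(0.975, sc$dof) * se
  expect_true(all(abs(dr - mu) <= bound + 1e-12))
})

test_that("residual diagnostics flag the right pathologies", {
  # exact fit: degenerate, no flags
  slc <- rep(c(10, 100), each = 2)
  d <- data.frame(load_value = slc,
                  pool_value = slc / exp(0.5 + 0.2 * log(slc)))
  expect_true(residual_diagnostics(fit_sc_model(d))$degenerate)

  # residuals from the true model: normality accepted in >= 90% of 100 reps
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    dd <- data.frame(load_value = exp(rnorm(200, 5, 0.3)))
    dd$pool_value <- dd$load_value /
      exp(1 + 0.3 * log(dd$load_value) + rnorm(200, 0, 0.1))
    residual_diagnostics(fit_sc_model(dd))$normality$p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  # injected variance trend raises the heteroscedasticity flag
  set.seed(21)
  x <- seq(1, 5, length.out = 300)
  y <- 2 + x + rnorm(300, 0, 0.05 * x^3)
  fake <- list(residuals = y - (2 + x), fitted = 2 + x)
  expect_true(residual_diagnostics(fake)$heteroscedasticity$flag)
})
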