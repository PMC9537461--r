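# The synthetic-process generator and its closed-form oracles.

test_that("the default process is deterministic and structurally valid", {
  ch1 <- make_default_process()
  ch2 <- make_default_process()
  expect_identical(ch1, ch2)
  expect_silent(validate_chain(ch1))
  expect_length(ch1$uos, 9L)
  expect_setequal(names(ch1$cqas), c("hcp", "aggregates", "monomer"))
  # one UO is flagged iac_equals_ds_spec (the all-LoQ viral filtration)
  flags <- unlist(lapply(ch1$uos, `[[`, "fallback"))
  expect_identical(unname(flags), "hcp")
  # model-type mix mirrors a realistic assignment matrix
  types <- unlist(lapply(ch1$uos, function(u) vapply(u$models, function(m)
    class(m)[1], character(1))))
  expect_setequal(unique(types),
                  c("manufacturing_sc", "sc_model", "doe_model",
                    "combined_model"))
})

test_that("the default process stays in its stated operating regime", {
  ch <- make_default_process()
  sim <- ipm_simulate(ch, sim_config(n_runs = 2000, seed = 5))
  for (cq in names(ch$cqas)) {
    d <- sim$ds[[cq]]
    expect_true(all(is.finite(d) & d > 0))
    oo <- oos_probability(d, ch$cqas[[cq]],
                          fit_scale = ch$cqas[[cq]]$fit_scale)
    expect_gt(oo$oos_probability, 0.001)
    expect_lt(oo$oos_probability, 0.2)
  }
  # the impurity spans decades from harvest to drug substance
  expect_gt(median(sim$pools$hcp[, "1"]) / median(sim$ds$hcp), 1e3)
})

test_that("the oracle chain's DS distribution is lognormal by construction", {
  ch <- make_oracle_chain(4)
  ok <- vapply(1:10, function(s) {
    sim <- ipm_simulate(ch, sim_config(n_runs = 4000, seed = s))
    shapiro.test(log(sim$ds$imp))$p.value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("manufacturing-run generation is reproducible and recovers truth", {
  ch <- make_oracle_chain(3)
  a <- generate_manufacturing_runs(ch, n = 10, seed = 4)
  b <- generate_manufacturing_runs(ch, n = 10, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$load_value > 0 & a$pool_value > 0))
  # recovery: fitted clearance distribution at UO2 vs truth (3 SE at n=200)
  big <- generate_manufacturing_runs(ch, n = 200, seed = 4)
  sel <- big$uo_id == 2 & big$cqa == "imp"
  m <- fit_manufacturing_sc(compute_specific_clearance(
    big$load_value[sel], big$pool_value[sel]))
  truth <- ch$uos[["2"]]$models$imp
  expect_lt(abs(m$mean_log - truth$mean_log),
            3 * truth$sd_log / sqrt(200))
})

test_that("DoE generation matches the documented run counts and ranges", {
  ch <- make_default_process()
  d2 <- generate_doe(ch, 2, seed = 1)    # OFAT, one factor
  expect_equal(nrow(d2), 5L)
  d6 <- generate_doe(ch, 6, seed = 1)    # 5x3-level design with one center
  expect_equal(nrow(d6), 11L)
  expect_length(unique(d6$elu_cond), 5L)
  expect_length(unique(d6$elu_pH), 3L)
  expect_equal(sum(d6$elu_cond == 12 & d6$elu_pH == 5.5), 1L)
  d8 <- generate_doe(ch, 8, seed = 1)    # face-centered CCD, 3 centers
  expect_equal(nrow(d8), 17L)
  for (f in attr(d8, "factors")) {
    rng <- ch$uos[["8"]]$models$aggregates$design_ranges[[f]]
    expect_true(all(d8[[f]] >= rng[1] - 1e-9 & d8[[f]] <= rng[2] + 1e-9))
  }
  expect_error(generate_doe(ch, 4, seed = 1), "no DoE-type model")
})

test_that("fitting generated DoE data recovers the generating coefficients", {
  ch <- make_default_process()
  truth <- ch$uos[["6"]]$models$hcp
  devs <- vapply(1:50, function(s) {
    d <- generate_doe(ch, 6, seed = s)
    m <- fit_doe_model(d, truth$factors, "response_hcp",
                       truth$design_ranges, design = "grid5x3")
    m$coef[["(Intercept)"]] - truth$coef[["(Intercept)"]]
  }, numeric(1))
  # intercept estimate is unbiased with se ~ resid_sd / sqrt(n)
  expect_lt(abs(mean(devs)), 3 * truth$residual_sd / sqrt(11 * 50))
})

test_that("end-to-end refit of the oracle chain reproduces its own closed form", {
  truth_chain <- make_oracle_chain(3)
  mfg <- generate_manufacturing_runs(truth_chain, n = 50, seed = 9)
  cqa <- truth_chain$cqas$imp
  uos <- lapply(1:3, function(k) {
    sel <- mfg$uo_id == k & mfg$cqa == "imp"
    unit_operation(k, paste0("UO", k), models = list(
      imp = fit_manufacturing_sc(compute_specific_clearance(
        mfg$load_value[sel], mfg$pool_value[sel]), cqa = cqa)))
  })
  l1 <- log(mfg$load_value[mfg$uo_id == 1 & mfg$cqa == "imp"])
  refit <- process_chain(uos, list(cqa), ranges = list(imp = c(1L, 3L)),
                         init = list(imp = list(mean_log = mean(l1),
                                                sd_log = sd(l1))))
  or <- analytic_chain_oracle(refit)
  n <- 4000L
  sim <- ipm_simulate(refit, sim_config(n_runs = n, seed = 10))
  ld <- log(sim$ds$imp)
  expect_lt(abs(mean(ld) - or$ds_mean_log), 3 * or$ds_sd_log / sqrt(n))
  expect_lt(abs(sd(ld) - or$ds_sd_log), 3 * or$ds_sd_log / sqrt(2 * n))
})

test_that("generated datasets round-trip through the CSV dialects", {
  ch <- make_default_process()
  mfg <- generate_manufacturing_runs(ch, n = 5, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_manufacturing_csv(mfg, f)
  back <- read_manufacturing_csv(f)
  expect_equal(back$load_value, mfg$load_value, tolerance = 1e-12)
  expect_equal(back$pool_value, mfg$pool_value, tolerance = 1e-12)
  expect_identical(back$pool_loq, mfg$pool_loq)
  expect_identical(back$batch_id, mfg$batch_id)

  doe <- generate_doe(ch, 6, seed = 3)
  fd <- tempfile(fileext = ".csv")
  write_doe_csv(doe, fd)
  back_doe <- read_doe_csv(fd)
  expect_equal(back_doe$response_hcp, doe$response_hcp, tolerance = 1e-12)
  expect_identical(attr(back_doe, "design"), "grid5x3")
  expect_identical(attr(back_doe, "uo_id"), 6L)
  expect_equal(attr(back_doe, "slc")[["hcp"]], attr(doe, "slc")[["hcp"]],
               tolerance = 1e-12)
})
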