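# NOR sampling and Monte-Carlo propagation through the chain.

test_that("NOR sampling matches the set-point and 3% CV", {
  pp <- process_parameter("pH", 7, cv = 0.03)
  set.seed(1)
  x <- sample_nor(pp, 1e5)
  expect_lt(abs(mean(x) - 7), 0.01)          # LLN
  expect_lt(abs(sd(x) - 0.21), 0.005)        # cv * set-point = 0.21
  tiny <- process_parameter("pH", 7, cv = 1e-12)
  expect_lt(max(abs(sample_nor(tiny, 100) - 7)), 1e-9)
  expect_error(sample_nor(process_parameter("z", 0, cv = 0.03), 1),
               "undefined")
})

test_that("uniform and truncated NOR variants keep location and spread", {
  set.seed(2)
  u <- sample_nor(process_parameter("pH", 7, 0.03, "uniform"), 1e5)
  expect_lt(abs(mean(u) - 7), 0.01)
  expect_lt(abs(sd(u) - 0.21), 0.01)         # variance-matched uniform
  tn <- sample_nor(process_parameter("pH", 7, 0.03, "truncated_normal"), 1e5)
  expect_true(all(abs(tn - 7) <= 3 * 0.21 + 1e-9))
})

test_that("deterministic chains compose exactly", {
  ch <- make_deterministic_chain(scs = 10, init = 100)
  expect_equal(unname(simulate_run(ch, "imp")), 10)
  ch2 <- make_deterministic_chain(scs = c(10, 5), init = 100)
  traj <- simulate_run(ch2, "imp")
  expect_equal(unname(traj), c(10, 2))
  sim <- ipm_simulate(ch2, sim_config(n_runs = 50, seed = 1))
  expect_equal(sim$ds$imp, rep(2, 50), tolerance = 1e-12)
})

test_that("pool overrides replace the unit operation's pool entirely", {
  ch <- make_deterministic_chain(scs = c(10, 5), init = 100)
  cfg <- sim_config(n_runs = 20, seed = 1)
  cfg$fixed_pool_overrides <- list("1:imp" = 50)
  sim <- ipm_simulate(ch, cfg)
  expect_equal(sim$ds$imp, rep(10, 20), tolerance = 1e-12)  # UO1 bypassed
  expect_true(all(sim$pools$imp[, "1"] == 50))
})

test_that("simulation is bit-for-bit reproducible for a fixed seed", {
  ch <- make_oracle_chain(3)
  s1 <- ipm_simulate(ch, sim_config(n_runs = 200, seed = 99))
  s2 <- ipm_simulate(ch, sim_config(n_runs = 200, seed = 99))
  expect_identical(s1$pools, s2$pools)
  s3 <- ipm_simulate(ch, sim_config(n_runs = 200, seed = 100))
  expect_false(identical(s1$ds$imp, s3$ds$imp))
})

test_that("lognormal chain matches the closed form within 3 MC SE", {
  ch <- make_oracle_chain(4)
  or <- analytic_chain_oracle(ch)
  n <- 4000L
  sim <- ipm_simulate(ch, sim_config(n_runs = n, seed = 5))
  ld <- log(sim$ds$imp)
  se_mean <- or$ds_sd_log / sqrt(n)
  se_sd <- or$ds_sd_log / sqrt(2 * n)
  expect_lt(abs(mean(ld) - or$ds_mean_log), 3 * se_mean)
  expect_lt(abs(sd(ld) - or$ds_sd_log), 3 * se_sd)
})

test_that("percent CQAs are capped at 100 and caps are counted", {
  cqa <- quality_attribute("mono", "purity", "%", ds_spec = 90)
  uo <- unit_operation(1, "step", models = list(
    mono = manufacturing_sc(log(1.2), 0.01, cqa = cqa,
                            response_kind = "yield")))
  ch <- process_chain(list(uo), list(cqa), ranges = list(mono = c(1L, 1L)),
                      init = list(mono = list(mean_log = log(95),
                                              sd_log = 0.01)))
  sim <- ipm_simulate(ch, sim_config(n_runs = 500, seed = 3))
  expect_true(all(sim$ds$mono <= 100))
  expect_identical(sim$n_capped[["mono"]], 500L)
})

test_that("an exploding chain aborts with a hard error", {
  cqa <- quality_attribute("mono", "purity", "%", ds_spec = 90)
  uo <- unit_operation(1, "step", models = list(
    mono = manufacturing_sc(900, 0, cqa = cqa, response_kind = "yield")))
  ch <- process_chain(list(uo), list(cqa), ranges = list(mono = c(1L, 1L)),
                      init = list(mono = list(mean_log = log(95),
                                              sd_log = 0.01)))
  expect_error(ipm_simulate(ch, sim_config(n_runs = 50, seed = 1)),
               "aborted")
})

test_that("imposed-load monotonicity: higher load never lowers the DS median", {
  cqa <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 10)
  sc <- ipmiac:::.make_sc_model(0.5, 0.3, 50, 0.1, spread_log = 0.3,
                                cqa = cqa)
  uo1 <- unit_operation(1, "a", models = list(
    imp = manufacturing_sc(1, 0.1, cqa = cqa)))
  uo2 <- unit_operation(2, "b", models = list(imp = sc))
  ch <- process_chain(list(uo1, uo2), list(cqa),
                      ranges = list(imp = c(1L, 2L)),
                      init = list(imp = list(mean_log = log(100),
                                             sd_log = 0.1)))
  meds <- vapply(c(20, 50, 120, 400), function(v) {
    cfg <- sim_config(n_runs = 2000, seed = 7)
    cfg$fixed_pool_overrides <- list("1:imp" = v)
    median(ipm_simulate(ch, cfg)$ds$imp)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("convergence scan is identically zero for a deterministic chain", {
  ch <- make_deterministic_chain(scs = c(10, 5), init = 100)
  cs <- convergence_scan(ch, "imp", cycles = c(20L, 50L), n_repeats = 5,
                         config = sim_config(seed = 1))
  expect_equal(cs$var_median, c(0, 0))
  expect_equal(cs$var_mad, c(0, 0))
  cs2 <- convergence_scan(ch, "imp", cycles = c(20L, 50L), n_repeats = 5,
                          config = sim_config(seed = 1), center = TRUE)
  expect_true(all(c("var_median_centered", "var_mad_centered") %in%
                    names(cs2)))
})
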