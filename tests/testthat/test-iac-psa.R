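# Screening grids, the OOS-vs-pool curve and acceptance-criteria inversion.

test_that("screening grid spans mean +/- 10 sd in 15 equidistant points", {
  imp <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 10)
  set.seed(1)
  v <- rnorm(10, 5, 0.1)
  g <- screening_grid(v, imp)
  expect_length(g$values, 15L)
  expect_equal(g$values[1], mean(v) - 10 * sd(v))
  expect_equal(g$values[15], mean(v) + 10 * sd(v))
  expect_equal(diff(g$values), rep(diff(g$values)[1], 14))
})

test_that("screening grid clips to positive values and the 100% cap", {
  imp <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 10)
  set.seed(2)
  v <- rnorm(10, 5, 1)   # mean - 10 sd < 0
  g <- screening_grid(v, imp)
  expect_gt(g$values[1], 0)
  expect_true(g$provenance$clipped)
  mono <- quality_attribute("mono", "purity", "%", ds_spec = 98)
  set.seed(3)
  vm <- rnorm(10, 99, 0.5)
  gm <- screening_grid(vm, mono)
  expect_lte(max(gm$values), 100)
  # purity grids run downward, toward the risky side
  expect_true(all(diff(gm$values) < 0))
  expect_error(screening_grid(rep(5, 10), imp), "iac_equals_ds_spec")
})

test_that("derive_iac interpolates the threshold crossing", {
  imp <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 10)
  fake <- structure(list(
    grid = structure(list(values = c(1, 2, 3), cqa = "imp",
                          provenance = list()), class = "screening_grid"),
    oos = c(0.01, 0.05, 0.20), uo_id = 1L, cqa = "imp", side = "upper",
    n_runs = 800L, seed = 1L, threshold = NA_real_, iac = NA_real_,
    smoothed_oos = NULL), class = "psa_result")
  out <- derive_iac(fake, 0.05)
  expect_equal(out$iac, 2)          # exact hit at a grid point
  expect_identical(out$status, "ok")

  fake$oos <- c(1e-4, 5e-4, 1e-3)   # never reaches the threshold
  expect_identical(derive_iac(fake, 0.05)$status, "not_derivable")
  expect_true(is.na(derive_iac(fake, 0.05)$iac))

  fake$oos <- c(0.2, 0.5, 0.9)      # already beyond at the first point
  expect_identical(derive_iac(fake, 0.05)$status, "not_derivable")

  fake$oos <- c(0.2, 0.01, 0.5)     # non-monotone raw curve: isotonic fit
  out2 <- derive_iac(fake, 0.05)
  expect_true(all(diff(out2$smoothed_oos) >= 0))
})

test_that("deterministic chain yields a step-function OOS curve", {
  # two deterministic clearances (product P = 50), upper DS limit 1:
  # OOS jumps 0 -> 1 exactly at imposed pool P * L = 50
  ch <- make_deterministic_chain(scs = c(10, 5), init = 100)
  grid <- structure(list(values = c(1, 3, 4.9, 5.1, 8, 12), cqa = "imp",
                         provenance = list()), class = "screening_grid")
  # override at UO1 leaves only UO2 downstream: step at 5 * 1 = 5
  psa <- psa_curve(ch, 1, "imp", grid, sim_config(n_runs = 20, seed = 1))
  expect_equal(psa$oos, as.numeric(grid$values / 5 > 1))
})

test_that("PSA curve matches the analytic tail on the oracle chain", {
  ch <- make_oracle_chain(4)
  mfg <- generate_manufacturing_runs(ch, n = 10, seed = 7)
  g <- screening_grid(mfg$pool_value[mfg$uo_id == 2 & mfg$cqa == "imp"],
                      ch$cqas$imp)
  psa <- psa_curve(ch, 2, "imp", g, sim_config(n_runs = 800, seed = 2))
  closed <- vapply(g$values, function(v)
    analytic_chain_oracle(ch, imposed_pool = v, uo_id = 2)$oos, numeric(1))
  # MC standard error of a tail probability at 800 runs, plus the small
  # upward bias of the 80%-upper-bound sd inflation
  se <- sqrt(pmax(closed * (1 - closed), 1e-4) / 800)
  expect_true(all(abs(psa$oos - closed) <= 4 * se + 0.01))
  # the isotonic inversion lands near the closed-form criterion
  iac_cf <- analytic_chain_oracle(ch)$iac_closed_form(0.05, at_uo = 2)
  out <- derive_iac(psa, 0.05)
  expect_lt(abs(out$iac - iac_cf) / iac_cf, 0.02)
})

test_that("closed-form inversion is the exact inverse of the closed-form OOS", {
  ch <- make_oracle_chain(4)
  or <- analytic_chain_oracle(ch)
  for (th in c(0.01, 0.05, 0.2)) {
    p <- or$iac_closed_form(th, at_uo = 2)
    expect_equal(analytic_chain_oracle(ch, imposed_pool = p, uo_id = 2)$oos,
                 th, tolerance = 1e-12)
  }
})

test_that("the iAC table applies DS-spec rules and the 3SD baseline", {
  ch <- make_oracle_chain(3)
  mfg <- generate_manufacturing_runs(ch, n = 10, seed = 5)
  tab <- derive_all_iacs(ch, mfg, sim_config(n_runs = 300, seed = 1))
  expect_equal(nrow(tab), 3L)
  last <- tab[tab$uo_id == 3, ]
  expect_identical(last$method, "ds_spec")
  expect_equal(last$iac, 10)         # the DS specification limit itself
  expect_true(all(tab$method[tab$uo_id < 3] == "psa"))
  expect_true(all(is.finite(tab$sd3_lower) & is.finite(tab$sd3_upper)))

  cmp <- compare_3sd(tab)
  expect_true("sd3_tighter" %in% names(cmp))
  expect_true(all(is.na(cmp$sd3_tighter[cmp$method != "psa"])))
})

test_that("fallback-flagged unit operations get the DS limit as iAC", {
  cqa <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 10)
  uo1 <- unit_operation(1, "a", models = list(
    imp = manufacturing_sc(1, 0.1, cqa = cqa)))
  uo2 <- unit_operation(2, "b", fallback = "imp")
  uo3 <- unit_operation(3, "c", models = list(
    imp = manufacturing_sc(0.5, 0.1, cqa = cqa)))
  ch <- process_chain(list(uo1, uo2, uo3), list(cqa),
                      ranges = list(imp = c(1L, 3L)),
                      init = list(imp = list(mean_log = log(100),
                                             sd_log = 0.1)))
  mfg <- generate_manufacturing_runs(ch, n = 10, seed = 2)
  tab <- derive_all_iacs(ch, mfg, sim_config(n_runs = 200, seed = 1))
  row2 <- tab[tab$uo_id == 2, ]
  expect_identical(row2$method, "ds_spec_fallback")
  expect_equal(row2$iac, 10)
})
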