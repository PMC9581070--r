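test_that("coverage is zero without drug and bounded by construction", {
  scn <- make_basic_scenario()
  m <- soa_model(scn)
  tc <- simulate_regimen(m, dose_regimen("sc", 0, n_doses = 1), t_end = 14)
  cv <- coverage(tc, "plasma")
  expect_equal(max(abs(cv$series$coverage)), 0, tolerance = 1e-8)
  expect_equal(cv$summary$peak, 0, tolerance = 1e-8)
  ## a hypothetical fully suppressed course reaches coverage 1
  tc$data$TS <- 0
  cv <- coverage(tc, "soa")
  expect_equal(cv$summary$peak, 1)
  ## zero baseline is undefined
  tc$baselines["soa"] <- 0
  expect_error(coverage(tc, "soa"), class = "soa_configuration_error")
})

test_that("coverage summary is computed on the steady-state cycle when flagged", {
  cs <- fixture_ccl20()
  m <- soa_model(cs$scenario)
  tc <- simulate_to_steady_state(m, cs$regimens$sc300_q2w)
  cv <- coverage(tc, "soa")
  expect_equal(cv$window, tc$ss_cycle)
  expect_gte(cv$summary$peak, cv$summary$trough)
  expect_true(cv$summary$trough > 0 && cv$summary$trough < 1)
})

test_that("steady-state AUC ratio of total drug recovers the geometry ratio", {
  ## binding off isolates the drug-distribution closure
  scn <- make_basic_scenario(kon = 0)  # ratio 0.3
  m <- soa_model(scn)
  reg <- dose_regimen("sc", 200, interval = 7, n_doses = 2)
  tc <- simulate_to_steady_state(m, reg, monitor = "drug")
  expect_true(tc$converged)
  expect_equal(auc_ratio(tc), 0.3, tolerance = 0.01)

  scn$soa <- soa_geometry(VS = 1.125, ratio = 0.2)
  tc <- simulate_to_steady_state(soa_model(scn), reg, monitor = "drug")
  expect_equal(auc_ratio(tc), 0.2, tolerance = 0.01)

  ## decoupled SoA: no drug ever reaches it
  scn$soa <- soa_geometry(VS = 0.5, ratio = 0)
  tc <- simulate_to_steady_state(soa_model(scn), reg, monitor = "drug")
  expect_equal(auc_ratio(tc), 0)

  ## a plain transient course has no steady-state cycle to integrate
  tc <- simulate_regimen(soa_model(scn), reg)
  expect_error(auc_ratio(tc), class = "soa_configuration_error")
})

test_that("required_affinity agrees with a grid scan and confirms its answer", {
  scn <- make_fast_scenario("monovalent")
  reg <- dose_regimen("sc", 300, interval = 7, n_doses = 2)
  threshold <- 0.5
  res <- required_affinity(scn, reg, threshold, statistic = "trough",
                           compartment = "soa", bracket = c(1e-4, 10),
                           max_weeks = 12)
  expect_equal(res$status, "ok")
  expect_gte(res$coverage, threshold)
  ## brute-force oracle: log-spaced grid scan of the same statistic
  grid_kd <- 10^seq(-4, 1, length.out = 26)
  stats <- vapply(grid_kd, function(kd) {
    tc <- simulate_to_steady_state(soa_model(set_affinity(scn, kd)), reg,
                                   max_weeks = 12)
    coverage(tc, "soa")$summary$trough
  }, numeric(1))
  ## coverage must be monotone non-increasing in KD for the scan to bracket
  expect_true(all(diff(stats) < 1e-6))
  last_ok <- max(which(stats >= threshold))
  expect_gte(res$KD_nM, grid_kd[last_ok] / 10^0.2)  # within one grid step
  expect_lte(res$KD_nM, grid_kd[last_ok + 1])
  ## 1.5x weaker than the returned affinity misses the threshold
  tc <- simulate_to_steady_state(soa_model(set_affinity(scn, 1.5 * res$KD_nM)),
                                 reg, max_weeks = 12)
  expect_lt(coverage(tc, "soa")$summary$trough, threshold)
})

test_that("required_affinity sentinels cover the trivial and impossible ends", {
  scn <- make_fast_scenario("monovalent")
  reg <- dose_regimen("sc", 300, interval = 7, n_doses = 2)
  res <- required_affinity(scn, reg, 0)
  expect_equal(res$status, "any")
  res <- required_affinity(scn, reg, 0.999999, compartment = "soa",
                           bracket = c(1e-3, 10), max_weeks = 12)
  expect_equal(res$status, "unachievable")
  expect_true(is.na(res$KD_nM))
})

test_that("coverage sweeps are monotone in affinity and dose", {
  scn <- make_fast_scenario("monovalent")
  reg <- dose_regimen("sc", 300, interval = 7, n_doses = 2)
  tab <- coverage_sweep(scn, reg, "KD", c(0.001, 0.1, 3), max_weeks = 12)
  expect_equal(tab$status, rep("ok", 3))
  expect_true(all(diff(tab$trough) < 0))        # weaker affinity, less coverage
  expect_true(attr(tab, "monotone_in_value"))
  tab <- coverage_sweep(scn, reg, "dose", c(0, 100, 300), max_weeks = 12)
  expect_equal(tab$trough[1], 0)                # no drug, no coverage
  expect_true(all(diff(tab$trough) > 0))        # more drug, more coverage
  expect_true(attr(tab, "monotone_in_value"))
})

test_that("sweep records per-point failures without aborting", {
  scn <- make_fast_scenario("monovalent")
  scn$pk$ka <- NA_real_  # SC dosing now impossible
  reg_sc <- dose_regimen("sc", 30, interval = 7, n_doses = 2)
  tab <- coverage_sweep(scn, reg_sc, "KD", c(0.01, 0.1), max_weeks = 8)
  expect_true(all(tab$status != "ok"))
  expect_true(all(is.na(tab$trough)))
})

test_that("local sensitivities behave like derivatives", {
  scn <- make_fast_scenario("monovalent", KD = 1)
  reg <- dose_regimen("sc", 300, interval = 7, n_doses = 2)
  tab <- local_sensitivity(scn, reg, c("dose", "KD"),
                           perturbation = 0.05, max_weeks = 12)
  expect_equal(tab$status, rep("ok", 2))
  ## more drug helps, weaker affinity hurts
  expect_gt(tab$sensitivity[tab$parameter == "dose"], 0)
  expect_lt(tab$sensitivity[tab$parameter == "KD"], 0)
  ## finite-difference consistency: 5% vs 10% steps agree to first order
  tab10 <- local_sensitivity(scn, reg, "dose", perturbation = 0.10,
                             max_weeks = 12)
  s5 <- tab$sensitivity[tab$parameter == "dose"]
  expect_lt(abs(tab10$sensitivity - s5) / abs(s5), 0.1)
  ## an invalid perturbation is reported per row, not fatal
  scn_edge <- scn
  scn_edge$pk <- pk_parameters(VP = 3, V2 = 2, Cl = 1, Q = 0.5, ka = 0.5,
                               F = 0.99)
  tab <- local_sensitivity(scn_edge, reg, c("F", "dose"), perturbation = 0.05,
                           max_weeks = 12)
  expect_true(tab$status[tab$parameter == "F"] != "ok")
  expect_true(tab$status[tab$parameter == "dose"] == "ok")
})
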