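test_that("the drug-free baseline is a fixed point of every variant", {
  for (valence in c("monovalent", "bivalent")) {
    scn <- make_basic_scenario(valence)
    m <- soa_model(scn)
    expect_lt(max(abs(m$rhs(0, m$state0, NULL)[[1]])), 1e-9)
  }
  ## competitor variant, both valences
  cs <- fixture_il33()
  m <- soa_model(cs$scenario)
  expect_lt(max(abs(m$rhs(0, m$state0, NULL)[[1]])), 1e-9)
  scn <- cs$scenario
  scn$binding <- binding_spec(KD = 0.01, valence = "monovalent")
  m <- soa_model(scn)
  expect_lt(max(abs(m$rhs(0, m$state0, NULL)[[1]])), 1e-9)
})

test_that("random scenarios all parametrize and close at baseline", {
  for (seed in 1:40) {
    scn <- random_scenario(seed)
    m <- soa_model(scn)
    expect_lt(max(abs(m$rhs(0, m$state0, NULL)[[1]])), 1e-9)
  }
})

test_that("without binding the target never feels the drug", {
  scn <- make_basic_scenario(kon = 0)
  m <- soa_model(scn)
  tc <- simulate_regimen(m, dose_regimen("iv", 300, n_doses = 1), t_end = 28)
  expect_equal(tc$data$TP, rep(scn$target$TP0, nrow(tc$data)), tolerance = 1e-8)
  expect_equal(tc$data$TS, rep(scn$target$TS0, nrow(tc$data)), tolerance = 1e-8)
  expect_equal(max(tc$data$CP), 0)
})

test_that("closed 1:1 binding relaxes to the closed-form equilibrium", {
  scn <- make_basic_scenario("monovalent", KD = 1, kon = 86.4)
  m <- soa_model(scn, rates = closed_binding_rates(scn))
  y0 <- m$state0
  y0[] <- 0
  y0["DP"] <- 1
  y0["TP"] <- 1
  tc <- simulate_regimen(m, dose_regimen("iv", 0, n_doses = 1), t_end = 2,
                         y0 = y0)
  last <- tc$data[nrow(tc$data), ]
  ## oracle: (1-C)^2 = KD*C with unit totals
  C_star <- equilibrium_complex_1to1(1, 1, 1)
  expect_equal(last$CP, C_star, tolerance = 1e-6)
  expect_equal(last$DP * last$TP / last$CP, 1, tolerance = 1e-6)
})

test_that("closed bivalent binding satisfies detailed balance with statistical factors", {
  scn <- make_basic_scenario("bivalent", KD = 1, kon = 86.4)
  m <- soa_model(scn, rates = closed_binding_rates(scn))
  y0 <- m$state0
  y0[] <- 0
  y0["DP"] <- 1
  y0["TP"] <- 1.5
  tc <- simulate_regimen(m, dose_regimen("iv", 0, n_doses = 1), t_end = 2,
                         y0 = y0)
  last <- tc$data[nrow(tc$data), ]
  kon <- scn$binding$kon
  koff <- scn$binding$koff
  expect_equal(last$CP / (last$DP * last$TP), 2 * kon / koff, tolerance = 1e-5)
  expect_equal(last$CP2 / (last$CP * last$TP), kon / (2 * koff), tolerance = 1e-5)
  ## mass conserved while relaxing
  expect_equal(max(abs(last$TP + last$CP + 2 * last$CP2 - 1.5)), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(last$DP + last$CP + last$CP2 - 1)), 0,
               tolerance = 1e-9)
})

test_that("closed-system trajectories conserve drug and target amounts", {
  for (valence in c("monovalent", "bivalent")) {
    scn <- make_basic_scenario(valence, KD = 0.5)
    m <- soa_model(scn, rates = closed_binding_rates(scn))
    y0 <- m$state0
    y0["DP"] <- 2
    y0["DS"] <- 1
    y0["DT"] <- 0.5
    tc <- simulate_regimen(m, dose_regimen("iv", 0, n_doses = 1), t_end = 5,
                           y0 = y0)
    r <- m$rates
    d_amt <- drug_amount(tc, scn, r)
    t_amt <- target_amount(tc, scn, r)
    expect_lt(max(abs(d_amt / d_amt[1] - 1)), 1e-6)
    expect_lt(max(abs(t_amt / t_amt[1] - 1)), 1e-6)
  }
})

test_that("switching off the second arm reduces the bivalent model to the monovalent one", {
  scn_m <- make_basic_scenario("monovalent", KD = 0.2)
  scn_b <- make_basic_scenario("bivalent", KD = 0.2)
  r <- derive_rates(scn_b)
  ## one-arm limit: first-arm kinetics identical to the 1:1 scheme
  r$kon1 <- r$kon
  r$kon2 <- 0
  m_b <- soa_model(scn_b, rates = r)
  m_m <- soa_model(scn_m)
  reg <- dose_regimen("iv", 150, n_doses = 2, interval = 7)
  grid <- seq(0, 21, by = 0.25)
  tc_b <- simulate_regimen(m_b, reg, t_end = 21, grid = grid)
  tc_m <- simulate_regimen(m_m, reg, t_end = 21, grid = grid)
  for (sp in c("DP", "TP", "CP", "TS", "CS")) {
    denom <- pmax(abs(tc_m$data[[sp]]), 1e-8)
    expect_lt(max(abs(tc_b$data[[sp]] - tc_m$data[[sp]]) / denom), 1e-3)
  }
  expect_equal(max(tc_b$data$CP2), 0)
})

test_that("competitor baseline complex matches the equilibrium formula", {
  cs <- fixture_il33()
  r <- derive_rates(cs$scenario)
  cmp <- cs$scenario$competitor
  expect_equal(r$SC0, cmp$kon * 0.0015 * 0.027 / (cmp$koff + cmp$kdeg_SC))
  expect_equal(r$SC0, 1.2176e-3, tolerance = 1e-4)
  ## competitor synthesis balances free and complexed losses
  expect_equal(r$ksyn_S, cmp$kdeg_S * cmp$S0 + cmp$kdeg_SC * r$SC0)
})

test_that("a zero-competitor system reproduces the plain model exactly", {
  cs <- fixture_il33()
  scn <- cs$scenario
  scn$competitor <- competitor_spec(S0 = 0, kon = 358, KD = 0.026,
                                    kdeg_S = 2.6, kdeg_SC = 2.6)
  m_c <- soa_model(scn)
  ## same closure without the competitor species
  scn_p <- scn
  scn_p$competitor <- NULL
  m_p <- soa_model(scn_p)
  reg <- dose_regimen("sc", 100, interval = 28, n_doses = 2)
  grid <- seq(0, 56, by = 0.5)
  tc_c <- simulate_regimen(m_c, reg, t_end = 56, grid = grid)
  tc_p <- simulate_regimen(m_p, reg, t_end = 56, grid = grid)
  for (sp in c("DP", "TP", "TS", "CP", "CS")) {
    expect_equal(tc_c$data[[sp]], tc_p$data[[sp]], tolerance = 1e-9)
  }
  expect_equal(max(abs(tc_c$data$S)), 0)
})

test_that("a drug-free competitor system holds every baseline for 100 days", {
  cs <- fixture_il33()
  m <- soa_model(cs$scenario)
  tc <- simulate_regimen(m, dose_regimen("sc", 0, n_doses = 1), t_end = 100)
  y0 <- m$state0
  for (sp in c("TP", "TS", "S", "SC")) {
    expect_lt(max(abs(tc$data[[sp]] / y0[[sp]] - 1)), 1e-4)
  }
})

test_that("the competitor scheme rejects unsupported synthesis/degradation splits", {
  cs <- fixture_il33()
  scn <- cs$scenario
  scn$target <- target_spec(TP0 = 0.0015, TS0 = 0.011, kdegTp = 4.2,
                            kdegTs = 1, frac = 1, Qtarget = 0.416)
  expect_error(derive_rates(scn), class = "soa_configuration_error")
  scn$target <- target_spec(TP0 = 0.0015, TS0 = 0.011, kdegTp = 4.2,
                            kdegTs = 0, frac = 0.5, Qtarget = 0.416)
  expect_error(derive_rates(scn), class = "soa_configuration_error")
})
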