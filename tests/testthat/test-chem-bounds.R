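test_that("ash-content assumptions bracket AFDW from dry weight", {
  expect_equal(afdw_bounds_from_dw(1.0), c(lower = 0.80, upper = 0.99))
  expect_equal(afdw_bounds_from_dw(2.5), c(lower = 2.00, upper = 2.475))
  for (dw in c(0.01, 0.7, 12)) {
    b <- afdw_bounds_from_dw(dw)
    expect_lt(b["lower"], b["upper"])
  }
  expect_error(afdw_bounds_from_dw(0), "positive")
})

test_that("cell-count biomass bounds ramp from 10 pg to the final weight", {
  counts <- c(1e11, 2e11, 4e11)
  b <- biomass_bounds_from_cells(counts, final_biomass = 8)
  expect_equal(b$lower[1], 1e11 * 10e-12) # 1.0 g/L at 10 pg
  expect_equal(b$lower[3], 8)             # ramp endpoint = final biomass
  expect_equal(b$upper[3], 8)
  expect_true(all(b$lower <= b$upper + 1e-12))
  # constant cell count: constant-weight upper series is constant
  b2 <- biomass_bounds_from_cells(rep(2e11, 4), final_biomass = 5)
  expect_equal(b2$upper, rep(5, 4))
  # final per-cell weight below 10 pg swaps the bounds
  expect_warning(b3 <- biomass_bounds_from_cells(c(1e11, 4e11), 0.002),
                 "swapping")
  expect_true(all(b3$lower <= b3$upper))
})

test_that("nitrate bounds follow the consumption polynomial and clamps", {
  flat <- list(lower = c(0.3, 0.3), upper = c(0.4, 0.4))
  b0 <- nitrate_bounds(100, flat, list(c0 = 0, c1 = 60, c2 = 0, c11 = 0))
  expect_equal(b0$lower, c(100, 100))
  expect_equal(b0$upper, c(100, 100))

  traj <- list(lower = c(0.2, 0.4), upper = c(0.2, 0.7))
  b1 <- nitrate_bounds(100, traj, list(c0 = 0, c1 = 60, c2 = 0, c11 = 0))
  expect_equal(b1$lower[2], 100 - 60 * 0.5) # upper biomass change 0.5 g/L
  expect_equal(b1$upper[2], 100 - 60 * 0.2)

  # consumption exceeding the initial pool clamps at zero
  big <- list(lower = c(0, 1), upper = c(0, 3))
  b2 <- nitrate_bounds(50, big, list(c0 = 0, c1 = 60, c2 = 0, c11 = 0))
  expect_equal(b2$lower[2], 0)
  # negative predicted consumption clamps to no consumption
  b3 <- nitrate_bounds(50, traj, list(c0 = 0, c1 = -60, c2 = 0, c11 = 0))
  expect_equal(b3$lower[2], 50)
  expect_equal(b3$upper[2], 50)
})

test_that("phosphorus-content assumptions give the phosphate bounds", {
  expect_equal(phosphate_bounds(20, list(lower = 0.2, upper = 0.4)),
               c(lower = 10, upper = 19))
  expect_equal(phosphate_bounds(20, list(lower = 0, upper = 0)),
               c(lower = 20, upper = 20))
  b <- phosphate_bounds(5, list(lower = 0.1, upper = 4))
  expect_true(b["lower"] <= b["upper"])
  expect_gte(b["lower"], 0)
})

test_that("pure water speciation hits the textbook anchors", {
  pure <- list(salinity = 0)
  neutral <- carbonate_equilibrium(pure, 25, 0)
  expect_equal(neutral$pH, 7.0, tolerance = 0.01)
  open_air <- carbonate_equilibrium(pure, 25, 10^-3.5)
  expect_equal(open_air$pH, 5.6, tolerance = 0.07)
})

test_that("carbonate state satisfies its own conservation laws", {
  media <- list(list(salinity = 0),
                generate_chem_fixture(15, 35, 4.2e-4),
                generate_chem_fixture(30, 20, 2e-3))
  for (m in media) {
    cs <- carbonate_equilibrium(m, if (is.null(m$temperature_C)) 25 else
      m$temperature_C, if (is.null(m$pCO2_atm)) 4.2e-4 else m$pCO2_atm)
    expect_lt(abs(cs$charge_residual), 1e-10)
    expect_equal(cs$DIC, cs$CO2aq + cs$HCO3 + cs$CO3)
    expect_true(all(c(cs$CO2aq, cs$HCO3, cs$CO3) >= 0))
  }
})

test_that("equilibrium pH decreases in pCO2 and matches a bisection oracle", {
  sw <- generate_chem_fixture(25, 35, 4.2e-4)
  phs <- vapply(10^seq(-5, -1, length.out = 20), function(p) {
    carbonate_equilibrium(sw, 25, p)$pH
  }, numeric(1))
  expect_true(all(diff(phs) < 0))

  set.seed(77)
  for (r in 1:8) {
    m <- generate_chem_fixture(runif(1, 5, 40), runif(1, 0, 40),
                               10^runif(1, -4.5, -2))
    got <- carbonate_equilibrium(m, m$temperature_C, m$pCO2_atm)$pH
    want <- oracle_carbonate_ph(m, m$temperature_C, m$pCO2_atm)
    expect_lt(abs(got - want), 0.05)
  }
})

test_that("residual model corrects the equilibrium pH on activity scale", {
  zero <- list(intercept = 0, dN = 0, dP = 0, vvm = 0)
  expect_equal(estimate_ph_with_residual(8, 1e-3, 1e-4, 0.5, zero), 8)
  shift <- list(intercept = 9e-8, dN = 0, dP = 0, vvm = 0)
  expect_equal(estimate_ph_with_residual(8, 0, 0, 0, shift), 7.0)
  up <- list(intercept = -1e-9, dN = 0, dP = 0, vvm = 0)
  expect_gt(estimate_ph_with_residual(8, 0, 0, 0, up), 8)
  # non-positive corrected activity clamps at the floor
  deep <- list(intercept = -1e-6, dN = 0, dP = 0, vvm = 0)
  expect_warning(ph <- estimate_ph_with_residual(8, 0, 0, 0, deep),
                 "clamped")
  expect_equal(ph, 12)
})

test_that("residual model fitting recovers known coefficients", {
  set.seed(5)
  n <- 40
  obs <- data.frame(equilibrium_ph = runif(n, 7, 9),
                    dN = runif(n, 0, 2e-3), dP = runif(n, 0, 1e-4),
                    vvm = runif(n, 0, 1))
  truth <- c(int = 2e-8, dN = 3e-5, dP = -2e-4, vvm = 5e-8)
  resid <- truth["int"] + truth["dN"] * obs$dN + truth["dP"] * obs$dP +
    truth["vvm"] * obs$vvm
  obs$real_ph <- -log10(10^(-obs$equilibrium_ph) + resid)
  fit <- fit_ph_residual_model(obs)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$model$dN, unname(truth["dN"]), tolerance = 1e-8)
  expect_equal(fit$model$vvm, unname(truth["vvm"]), tolerance = 1e-8)

  # zero residuals give zero coefficients
  obs0 <- obs; obs0$real_ph <- obs0$equilibrium_ph
  fit0 <- fit_ph_residual_model(obs0)
  expect_equal(fit0$model$dN, 0, tolerance = 1e-15)

  # noisy recovery within 3 SE
  set.seed(6)
  noisy <- obs
  noisy$real_ph <- -log10(10^(-obs$equilibrium_ph) + resid +
                            rnorm(n, 0, 2e-9))
  fitn <- fit_ph_residual_model(noisy)
  lmfit <- lm(I(10^(-noisy$real_ph) - 10^(-noisy$equilibrium_ph)) ~
                dN + dP + vvm, data = noisy)
  se <- summary(lmfit)$coefficients["dN", "Std. Error"]
  expect_lt(abs(fitn$model$dN - truth["dN"]), 3 * se)

  expect_error(fit_ph_residual_model(obs[1:3, ]), "at least 5")
  degen <- obs; degen$dP <- degen$dN
  expect_error(fit_ph_residual_model(degen), "rank-deficient")
})

test_that("illumination bounds invert the assumed diameter range", {
  b <- illumination_bounds(100, c(0.05, 0.10), 1)
  expect_equal(unname(b), c(2 * 100 / 0.10, 2 * 100 / 0.05))
  expect_lt(b["lower"], b["upper"])
})
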