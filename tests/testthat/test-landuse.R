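test_that("stem counts reproduce the documented thinning outcomes", {
  teak <- tree_system(1110, c(4, 10), c(0.6, 0.5))
  alley <- tree_system(555, c(5, 10), c(0.5, 0.5))
  silvo <- tree_system(200)
  expect_equal(stem_count(teak, 20), 222)
  expect_equal(stem_count(alley, 20), 138.75)   # reported as 139
  expect_equal(round(stem_count(alley, 20)), 139)
  expect_equal(stem_count(silvo, 20), 200)
  # before any thinning the initial density stands
  expect_equal(stem_count(teak, 0), 1110)
  expect_equal(stem_count(teak, 3), 1110)
  expect_equal(stem_count(teak, 4), 1110 * 0.4)
  # mortality compounds multiplicatively
  expect_equal(stem_count(silvo, 20, include_mortality = TRUE),
               200 * 0.995^20)
})

test_that("tree system constructor validates thinning schedules", {
  expect_error(tree_system(100, c(10, 4), c(0.5, 0.5)), "increasing")
  expect_error(tree_system(100, 25, 0.5), "increasing")
  expect_error(tree_system(100, 4, 1.5))
})

test_that("stocking rate follows the canopy-weighted area rule", {
  # 36% of the initial pasture area under canopy by year 20
  expect_equal(stocking_rate(1.9, 0.95, 0.95 * 0.64, 0.95 * 0.36), 1.558)
  expect_equal(stocking_rate(1.9, 0.95, 0.95, 0), 1.9)        # no shading
  expect_equal(stocking_rate(2, 1, 0, 1), 1)                  # full canopy
  expect_error(stocking_rate(2, 0, 0, 0), "positive")
  expect_error(stocking_rate(2, 1, 0.8, 0.4), "exceed")
})

test_that("clearing circles reduce the cultivable area", {
  expect_equal(cultivable_area_fraction(555, 1), 1 - 555 * pi / 1e4)
  expect_equal(round(100 * (1 - cultivable_area_fraction(555, 1))), 17)
  expect_equal(cultivable_area_fraction(0, 1), 1)
  expect_equal(cultivable_area_fraction(200, 1), 1 - 200 * pi / 1e4)
  expect_equal(cultivable_area_fraction(1e6, 1), 0)  # floored
})

test_that("npv matches a brute-force discounting loop", {
  expect_equal(npv(c(-100, 105), 0.05), 0)
  expect_equal(npv(rep(0, 21), 0.05), 0)
  set.seed(42)
  for (r in c(0, 0.05, 0.12)) {
    ncf <- rnorm(21, 0, 500)
    brute <- 0
    for (t in 0:20) brute <- brute + ncf[t + 1] / (1 + r)^t
    expect_equal(npv(ncf, r), brute)
  }
  expect_error(npv(c(1, 2), -1), "discount rate")
})

test_that("discounted payback follows the documented conventions", {
  expect_equal(discounted_payback(rep(0, 21), 0.05), 0)        # forest
  expect_equal(discounted_payback(c(10, rep(-1, 20)), 0.05), 0)
  # costs throughout, single large final harvest: pays back in year T
  teak_like <- c(-2000, rep(-100, 19), 20000)
  expect_equal(discounted_payback(teak_like, 0.05), 20)
  # never positive: assigned the final year
  expect_equal(discounted_payback(c(-100, rep(1, 20)), 0.05), 20)
  # decreasing any single revenue entry never shortens the payback
  set.seed(7)
  for (k in 1:20) {
    ncf <- c(-800, rnorm(20, 100, 150))
    p0 <- discounted_payback(ncf, 0.05)
    j <- sample(21, 1)
    ncf[j] <- ncf[j] - runif(1, 0, 300)
    expect_gte(discounted_payback(ncf, 0.05), p0)
  }
})

test_that("net cash flow is revenue minus cost with area factors baked in", {
  fx <- make_default_fixture(seed = 1)
  # forest: no costs, no revenues, any year
  for (t in c(0, 7, 20))
    expect_equal(net_cash_flow(fx$land_uses$forest, t, prices = fx$prices), 0)
  # revenue identity on a minimal hand-built spec
  spec <- list(name = "toy", quantities = list(maize = rep(2, 3)),
               cost_schedule = rep(0, 3), prices = c(maize = 10))
  expect_equal(net_cash_flow(spec, 1, list(maize = list(yield = 1, price = 1))),
               20)
  expect_equal(net_cash_flow(spec, 1, list(maize = list(yield = 2, price = 3))),
               120)
  expect_error(net_cash_flow(spec, 1, list(rice = list(yield = 1, price = 1))),
               "missing draw")
  # fixture rice at year 0: independent hand sum from the parameter file
  p <- fx$params
  hand <- p$rice_yield * p$rice_price -
    (p$clearing_cost + p$rice_inputs_year0 + p$rice_labour * p$wage)
  expect_equal(net_cash_flow(fx$land_uses$rice, 0, prices = fx$prices), hand)
})

test_that("npv is linear in prices when costs are zero", {
  fx <- make_default_fixture(seed = 1)
  spec <- fx$land_uses$alley_cropping
  spec$cost_schedule[] <- 0
  ncf1 <- vapply(0:20, function(t) net_cash_flow(spec, t, prices = fx$prices),
                 numeric(1))
  ncf2 <- vapply(0:20, function(t) net_cash_flow(spec, t, prices = fx$prices * 2),
                 numeric(1))
  expect_equal(npv(ncf2, 0.05), 2 * npv(ncf1, 0.05))
})

test_that("food energy averages crop and meat yields, timber excluded", {
  fx <- make_default_fixture(seed = 1)
  expect_equal(food_energy(fx$land_uses$teak_plantation, fx$energy_factors), 0)
  # constant yield times factor
  toy <- list(quantities = list(rice = rep(100, 21)),
              cost_schedule = rep(0, 21))
  expect_equal(food_energy(toy, c(rice = 2)), 200)
  expect_error(food_energy(toy, c(maize = 2)), "missing energy factor")
  # alley cropping: year-by-year hand sum
  alley <- fx$land_uses$alley_cropping
  hand <- sum(alley$quantities$maize * fx$energy_factors[["maize"]]) / 21
  expect_equal(food_energy(alley, fx$energy_factors), hand)
})

test_that("deterministic evaluation reproduces the calibration contracts", {
  fx <- make_default_fixture(seed = 1)
  et <- expected_indicators(fx)
  expect_equal(unname(et$mean["forest", ]), rep(0, 5))
  expect_equal(et$mean["teak_plantation", "payback"], 20)
  expect_equal(et$mean["rice", "payback"], 0)
  expect_equal(et$mean["rice", "labour"], 32)
  expect_equal(et$mean["pasture", "labour"], 8)
  # food ordering: maize >> rice > alley > pasture > silvopasture, timber 0
  f <- et$mean[, "food"]
  expect_true(f[["maize"]] > f[["rice"]], )
  expect_true(f[["rice"]] > f[["alley_cropping"]])
  expect_true(f[["alley_cropping"]] > f[["pasture"]])
  expect_true(f[["pasture"]] > f[["silvopasture"]])
  expect_equal(f[["teak_plantation"]], 0)
  # the silvopasture stocking path never increases over the rotation
  stock <- fx$land_uses$silvopasture$shading$stocking_path
  expect_true(all(diff(stock) <= 0))
  expect_equal(stock[1], 1.9)
})

test_that("monte-carlo results are reproducible and degenerate correctly", {
  fx <- make_default_fixture(seed = 1)
  a <- simulate_indicators(fx, n_reps = 200, seed = 9)
  b <- simulate_indicators(fx, n_reps = 200, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, simulate_indicators(fx, n_reps = 200, seed = 10)))

  # forest stays 0 +/- 0 under any number of repetitions
  expect_equal(unname(a$mean["forest", ]), rep(0, 5))
  expect_equal(unname(a$sd["forest", ]), rep(0, 5))

  # constant histories and zero input cv remove all stochasticity
  flat <- perturb_fixture(fx, list(history_cv = 0 * fx$params$history_cv))
  d <- simulate_indicators(flat, n_reps = 50, seed = 1, input_cv = 0)
  expect_true(all(d$sd == 0))
  expect_equal(d$mean, expected_indicators(flat)$mean, tolerance = 1e-9)
})

test_that("monte-carlo means converge with the repetition count", {
  fx <- make_default_fixture(seed = 1)
  a <- simulate_indicators(fx, n_reps = 10000, seed = 21)
  b <- simulate_indicators(fx, n_reps = 100000, seed = 22)
  for (lu in c("maize", "silvopasture")) {
    se <- sqrt(a$sd[lu, "npv"]^2 / 10000 + b$sd[lu, "npv"]^2 / 100000)
    expect_lt(abs(a$mean[lu, "npv"] - b$mean[lu, "npv"]), 2 * se)
  }
})
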