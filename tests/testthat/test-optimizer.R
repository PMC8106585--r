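test_that("worst-case coefficients shift unfavourably by m standard deviations", {
  expect_equal(worst_case_coefficient(8066, 2643, 0, "more"), 8066)
  expect_equal(worst_case_coefficient(8066, 2643, 3, "more"), 137)
  expect_equal(worst_case_coefficient(8, 0.2, 1.5, "less"), 8.3)
  expect_equal(worst_case_coefficient(5, 1, 2, "more"), 3)
  expect_error(worst_case_coefficient(5, -1, 2, "more"))
  expect_error(worst_case_coefficient(5, 1, -2, "more"))
})

test_that("scenario enumeration covers all worst-case subsets", {
  expect_equal(nrow(enumerate_scenarios(1)), 2)
  expect_equal(nrow(enumerate_scenarios(2)), 4)
  expect_equal(nrow(enumerate_scenarios(7)), 128)
  expect_equal(anyDuplicated(enumerate_scenarios(7)), 0)
  expect_error(enumerate_scenarios(21), "refusing")
})

test_that("normalised distances span 0 (target met) to 100 (worst case)", {
  expect_equal(normalize_distance(10, 10, 2, "more"), 0)
  expect_equal(normalize_distance(2, 10, 2, "more"), 100)
  expect_equal(normalize_distance(6, 10, 2, "more"), 50)
  expect_equal(normalize_distance(6, 2, 10, "less"), 50)
  expect_equal(normalize_distance(15, 10, 2, "more"), 0)    # clipped
  expect_equal(normalize_distance(0, 10, 2, "more"), 100)   # clipped
  expect_equal(normalize_distance(5, 7, 7, "more"), 0)      # degenerate
})

test_that("a single land use forces the whole farm onto it", {
  tab <- baseline_coefficients()
  one <- subtable(tab, "maize")
  pf <- optimize_portfolio(one, m = 1.5)
  expect_equal(unname(pf$shares), 1)
})

test_that("shares are a valid composition and respect forced zeros", {
  tab <- baseline_coefficients()
  for (m in c(0, 1.5, 3)) {
    pf <- optimize_portfolio(tab, m = m)
    expect_true(all(pf$shares >= 0))
    expect_equal(sum(pf$shares), 1, tolerance = 1e-9)
    expect_gte(pf$beta, 0)
  }
  pf <- optimize_portfolio(tab, m = 0, forced_zero = c("maize", "forest"))
  expect_equal(unname(pf$shares["maize"]), 0)
  expect_equal(unname(pf$shares["forest"]), 0)
  expect_error(optimize_portfolio(tab, m = 0, forced_zero = "orchard"),
               "unknown land use")
})

test_that("reported beta equals the brute-force worst distance of the shares", {
  tab <- baseline_coefficients()
  for (m in c(0, 3)) {
    pf <- optimize_portfolio(tab, m = m)
    expect_equal(pf$beta, oracle_worst_distance(tab, pf$shares, m),
                 tolerance = 1e-6)
  }
})

test_that("optimal beta is non-decreasing in the uncertainty multiple", {
  tab <- baseline_coefficients()
  betas <- vapply(c(0, 0.5, 1, 1.5, 2, 3), function(m)
    optimize_portfolio(tab, m = m)$beta, numeric(1))
  expect_true(all(diff(betas) >= -1e-9))
})

test_that("adding a constraint never improves the guaranteed worst case", {
  tab <- baseline_coefficients()
  base <- optimize_portfolio(tab, m = 3)
  capped <- optimize_portfolio(tab, m = 3, labour_cap = 12)
  expect_gte(capped$beta, base$beta - 1e-9)
  inv <- optimize_portfolio(tab, m = 3, investment_cap = 800)
  expect_gte(inv$beta, base$beta - 1e-9)
})

test_that("solutions are invariant to uniform weight rescaling", {
  tab <- baseline_coefficients()
  w1 <- setNames(rep(1, 5), tab$indicators)
  pf1 <- optimize_portfolio(tab, m = 1.5, weights = w1)
  pf5 <- optimize_portfolio(tab, m = 1.5, weights = 5 * w1)
  expect_equal(pf1$shares, pf5$shares, tolerance = 1e-6)
  expect_equal(pf5$beta, 5 * pf1$beta, tolerance = 1e-6)
})

test_that("LP optimum matches the exhaustive simplex grid on 3-land-use tables", {
  tab <- baseline_coefficients()
  combos <- combn(tab$land_uses, 3)
  for (j in seq_len(ncol(combos))) {
    sub <- subtable(tab, combos[, j])
    pf <- optimize_portfolio(sub, m = 1.5)
    grid <- oracle_grid_beta(sub, m = 1.5, step = 0.01)
    expect_lte(pf$beta, grid + 1e-5)
    expect_lte(grid - pf$beta, 2)   # grid resolution allowance
  }
})

test_that("the two-scenario relaxation bounds the full enumeration from below", {
  tab <- baseline_coefficients()
  for (m in c(1.5, 3)) {
    full <- optimize_portfolio(tab, m = m)$beta
    rows <- oracle_distance_rows(tab, m)
    # keep only the all-predicted and all-worst-case scenario per indicator:
    # rebuild them independently
    L <- length(tab$land_uses)
    relax <- NULL
    for (i in tab$indicators) {
      dir <- tab$directions[[i]]
      mu <- tab$mean[, i]
      wc <- if (dir == "more") mu - m * tab$sd[, i] else mu + m * tab$sd[, i]
      for (cc in list(mu, wc)) {
        tgt <- if (dir == "more") max(cc) else min(cc)
        wst <- if (dir == "more") min(cc) else max(cc)
        if (abs(tgt - wst) < 1e-12) next
        d <- if (dir == "more") 100 * (tgt - cc) / (tgt - wst)
             else 100 * (cc - tgt) / (wst - tgt)
        relax <- rbind(relax, d)
      }
    }
    sol <- boot::simplex(a = c(rep(0, L), 1),
                         A1 = cbind(relax, -1), b1 = rep(0, nrow(relax)),
                         A3 = matrix(c(rep(1, L), 0), 1), b3 = 1,
                         maxi = FALSE)
    expect_lte(sol$soln[L + 1], full + 1e-6)
  }
})

test_that("infeasible constraint sets raise a typed error", {
  tab <- baseline_coefficients()
  expect_error(optimize_portfolio(tab, m = 3, labour_cap = -5),
               class = "lu_infeasible")
})

test_that("bray-curtis dissimilarity behaves as a compositional distance", {
  expect_equal(bray_curtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(bray_curtis(c(1, 0, 0), c(0, 0.5, 0.5)), 1)
  expect_equal(bray_curtis(c(0.6, 0.4, 0), c(0.2, 0.4, 0.4)), 0.4)
  expect_error(bray_curtis(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(bray_curtis(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
  # bounds on random compositions
  set.seed(1)
  for (k in 1:20) {
    p <- runif(7); p <- p / sum(p)
    q <- runif(7); q <- q / sum(q)
    bc <- bray_curtis(p, q)
    expect_gte(bc, 0); expect_lte(bc, 1)
    expect_equal(bc, bray_curtis(q, p))
  }
})
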