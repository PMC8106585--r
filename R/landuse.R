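#' Standing stems of a tree system at a given year
#'
#' Initial planting density reduced multiplicatively by every thinning that
#' has taken place by \code{year}, and optionally by annual mortality
#' (0.5%/yr by default in the shipped tree systems).
#'
#' @param system A tree system list with \code{initial_density},
#'   \code{thinnings} (data frame with \code{year}, \code{fraction}) and
#'   \code{mortality}.
#' @param year Year in \code{0..harvest_year}.
#' @param include_mortality Apply the annual mortality reduction?
#' @return Stems per hectare (unrounded).
#' @export
#' @examples
#' teak <- tree_system(1110, thin_years = c(4, 10), thin_fractions = c(0.6, 0.5))
#' stem_count(teak, 20)  # 222
stem_count <- function(system, year, include_mortality = FALSE) {
  stopifnot(year >= 0, year <= system$harvest_year)
  s <- system$initial_density
  th <- system$thinnings
  if (!is.null(th) && nrow(th))
    for (j in seq_len(nrow(th)))
      if (th$year[j] <= year) s <- s * (1 - th$fraction[j])
  if (include_mortality) s <- s * (1 - system$mortality)^year
  s
}

#' Construct a tree system
#'
#' @param initial_density Stems per hectare at planting.
#' @param thin_years,thin_fractions Thinning years (strictly increasing,
#'   within the rotation) and fractions removed.
#' @param mortality Annual mortality rate (fraction).
#' @param harvest_year Final harvest year.
#' @param canopy_fraction_schedule Optional fraction of the plot under canopy
#'   for each year 0..harvest_year.
#' @return A list of class \code{tree_system}.
#' @export
tree_system <- function(initial_density, thin_years = numeric(),
                        thin_fractions = numeric(), mortality = 0.005,
                        harvest_year = 20, canopy_fraction_schedule = NULL) {
  stopifnot(initial_density >= 0, length(thin_years) == length(thin_fractions),
            all(thin_fractions >= 0 & thin_fractions <= 1),
            mortality >= 0 && mortality < 1)
  if (length(thin_years) &&
      (any(diff(thin_years) <= 0) || any(thin_years <= 0) ||
       any(thin_years >= harvest_year)))
    stop("thinning years must be strictly increasing and within (0, harvest_year)")
  structure(list(initial_density = initial_density,
                 thinnings = data.frame(year = thin_years,
                                        fraction = thin_fractions),
                 mortality = mortality, harvest_year = harvest_year,
                 canopy_fraction_schedule = canopy_fraction_schedule),
            class = "tree_system")
}

#' Silvopasture stocking rate under partial canopy
#'
#' Linearly reduces the stocking rate in proportion to the pasture area under
#' tree canopy, where shaded pasture supports only half the stock of pasture
#' in full sun.
#'
#' @param S0 Initial stocking rate (cows/ha).
#' @param A0 Initial pasture area (ha).
#' @param A_sun,A_canopy Pasture area in full sun and under canopy (ha);
#'   their sum must not exceed \code{A0}.
#' @return Stocking rate (cows/ha).
#' @export
#' @examples
#' stocking_rate(1.9, 0.95, 0.95 * 0.64, 0.95 * 0.36)  # 1.558
stocking_rate <- function(S0, A0, A_sun, A_canopy) {
  if (A0 <= 0) stop("initial pasture area must be positive")
  stopifnot(A_sun >= 0, A_canopy >= 0)
  if (A_sun + A_canopy > A0 + 1e-9)
    stop("sun and canopy areas exceed the initial pasture area")
  S0 * (A_sun + 0.5 * A_canopy) / A0
}

#' Cultivable area fraction after tree clearing circles
#'
#' Each tree seedling is kept clear of vegetation within a fixed radius,
#' removing that circle from crop cultivation.
#'
#' @param density Trees per hectare.
#' @param clear_radius Clearing radius around each seedling (m).
#' @return Fraction of the hectare remaining cultivable (floored at 0).
#' @export
#' @examples
#' cultivable_area_fraction(555, 1)  # 0.826, i.e. a 17% reduction
cultivable_area_fraction <- function(density, clear_radius) {
  stopifnot(density >= 0, clear_radius >= 0)
  max(0, 1 - density * pi * clear_radius^2 / 1e4)
}

#' Net cash flow of a land use in one year
#'
#' Revenue (summed over commodities: quantity times yield multiplier times
#' price times price multiplier) minus the year's total costs. Quantity
#' schedules already include usable-area and shading factors, the silvopasture
#' stocking path and timber volumes at thinning/harvest years.
#'
#' @param spec A land-use spec from a [make_default_fixture()] fixture.
#' @param year Year in 0..T.
#' @param draws Named list: for every commodity the spec references, a list
#'   with elements \code{yield} and \code{price} (multipliers for this year).
#'   Defaults to unit multipliers.
#' @param prices Named price vector per commodity (taken from the fixture).
#' @return Net cash flow in $/ha.
#' @export
net_cash_flow <- function(spec, year, draws = NULL, prices = NULL) {
  stopifnot(year >= 0, year < length(spec$cost_schedule))
  rev <- 0
  for (cm in names(spec$quantities)) {
    q <- spec$quantities[[cm]][year + 1]
    if (q == 0) next
    d <- if (is.null(draws)) list(yield = 1, price = 1) else draws[[cm]]
    if (is.null(d)) stop("missing draw for commodity '", cm, "'")
    p <- if (is.null(prices)) spec$prices[[cm]] else prices[[cm]]
    if (is.null(p)) stop("missing price for commodity '", cm, "'")
    rev <- rev + q * d$yield * p * d$price
  }
  rev - spec$cost_schedule[year + 1]
}

#' Net present value of a cash-flow series
#'
#' @param ncf Net cash flows for years 0..T.
#' @param rate Discount rate per year (greater than -1).
#' @return NPV in the units of \code{ncf}.
#' @export
#' @examples
#' npv(c(-100, 105), 0.05)  # 0
npv <- function(ncf, rate) {
  if (rate <= -1) stop("discount rate must exceed -1")
  sum(ncf * (1 + rate)^(-(seq_along(ncf) - 1)))
}

#' Discounted payback period
#'
#' The first year whose cumulative discounted net cash flow is positive.
#' An all-zero series pays back immediately (0); a series whose cumulative
#' discounted cash flow never turns positive is assigned the final year T,
#' the convention under which a plantation paying off only at the final
#' harvest has payback T.
#'
#' @inheritParams npv
#' @return Payback year (integer in 0..T).
#' @export
discounted_payback <- function(ncf, rate) {
  if (rate <= -1) stop("discount rate must exceed -1")
  cum <- cumsum(ncf * (1 + rate)^(-(seq_along(ncf) - 1)))
  pos <- which(cum > 1e-9)
  if (!length(pos)) return(if (all(ncf == 0)) 0L else length(ncf) - 1L)
  as.integer(pos[1] - 1L)
}

#' Mean annual dietary-energy production of a land use
#'
#' Converts the food-commodity quantity schedules (crops and meat; timber
#' excluded) to dietary energy and averages over the rotation.
#'
#' @param spec A land-use spec.
#' @param energy_factors Named vector, Mcal per yield unit per food commodity.
#' @param yield_multipliers Optional named list of per-year yield multiplier
#'   vectors (default 1).
#' @return Mcal/ha/yr.
#' @export
food_energy <- function(spec, energy_factors, yield_multipliers = NULL) {
  years <- length(spec$cost_schedule)
  total <- 0
  for (cm in names(spec$quantities)) {
    if (!cm %in% names(energy_factors)) {
      if (cm %in% c("teak", "cedar", "timber")) next
      stop("missing energy factor for food commodity '", cm, "'")
    }
    q <- spec$quantities[[cm]]
    mult <- if (is.null(yield_multipliers)) 1 else yield_multipliers[[cm]]
    total <- total + sum(q * mult) * energy_factors[[cm]]
  }
  total / years
}

# Deterministic indicator vector for one land-use spec (unit multipliers).
indicator_vector <- function(spec, fixture) {
  years <- fixture$horizon + 1
  ncf <- vapply(0:(years - 1), function(t)
    net_cash_flow(spec, t, prices = fixture$prices), numeric(1))
  c(npv = npv(ncf, fixture$discount_rate),
    payback = discounted_payback(ncf, fixture$discount_rate),
    food = food_energy(spec, fixture$energy_factors),
    labour = mean(spec$labour_schedule),
    investment = spec$cost_schedule[1])
}

#' Deterministic indicator table of a fixture
#'
#' Evaluates all five indicators for every land use at expected yields,
#' prices, labour and investment (all multipliers 1). Useful for audits and
#' as the degenerate (no-uncertainty) limit of [simulate_indicators()].
#'
#' @param fixture A study fixture.
#' @return An [indicator_table] with all standard deviations zero.
#' @export
expected_indicators <- function(fixture) {
  mu <- t(vapply(fixture$land_uses, indicator_vector, numeric(5),
                 fixture = fixture))
  indicator_table(mu, 0 * mu)
}

# one truncated-normal multiplier per repetition (truncation at zero)
rtrunc_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  x <- stats::rnorm(n, 1, cv)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), 1, cv)
  x
}

#' Monte-Carlo simulation of the indicator coefficients
#'
#' For each repetition, per-year yield and price multipliers are bootstrap
#' resampled (i.i.d. across years) from the mean-normalised, detrended
#' historical series held in the fixture; labour demand and investment costs
#' are drawn with a 10% coefficient of variation (normal, truncated at zero)
#' around their expected values. Indicator means and standard deviations over
#' repetitions are returned per land use.
#'
#' @param fixture A study fixture from [make_default_fixture()].
#' @param n_reps Number of Monte-Carlo repetitions (10,000 for
#'   production-quality coefficients).
#' @param seed Integer seed; a fixed seed gives an identical result.
#' @param input_cv Coefficient of variation for labour and investment draws.
#' @return An [indicator_table] (subclass \code{mc_result}) carrying
#'   \code{n_reps}.
#' @export
simulate_indicators <- function(fixture, n_reps = 10000, seed = 1,
                                input_cv = 0.10) {
  stopifnot(n_reps >= 1)
  set.seed(as.integer(seed))
  years <- fixture$horizon + 1
  disc <- (1 + fixture$discount_rate)^(-(0:(years - 1)))
  pools <- lapply(fixture$histories, relative_deviations)

  draw_mat <- function(pool_name) {
    if (is.null(pools[[pool_name]])) return(NULL)  # no variability recorded
    matrix(sample(pools[[pool_name]], n_reps * years, replace = TRUE),
           n_reps, years)
  }

  inds <- lu_indicators()$indicator
  mu <- sd <- matrix(0, length(fixture$land_uses), length(inds),
                     dimnames = list(names(fixture$land_uses), inds))
  for (lu in names(fixture$land_uses)) {
    spec <- fixture$land_uses[[lu]]
    if (spec$landcover_class == "protective") next   # all-zero by invariant
    rev <- matrix(0, n_reps, years)
    food <- matrix(0, n_reps, years)
    for (cm in names(spec$quantities)) {
      q <- spec$quantities[[cm]]
      if (all(q == 0)) next
      ym <- draw_mat(paste0(cm, "_yield")); if (is.null(ym)) ym <- 1
      pm <- draw_mat(paste0(cm, "_price")); if (is.null(pm)) pm <- 1
      qy <- sweep(if (is.matrix(ym)) ym else matrix(1, n_reps, years),
                  2, q, `*`)
      rev <- rev + qy * pm * fixture$prices[[cm]]
      if (cm %in% names(fixture$energy_factors))
        food <- food + qy * fixture$energy_factors[[cm]]
    }
    lab_mult <- rtrunc_mult(n_reps, input_cv)
    inv_mult <- rtrunc_mult(n_reps, input_cv)
    labour_cost <- spec$labour_schedule * fixture$wage
    cost <- matrix(rep(spec$input_schedule + labour_cost, each = n_reps),
                   n_reps, years)
    # labour variability scales running labour costs; investment variability
    # scales the year-0 (establishment) outlay
    cost[, -1] <- cost[, -1] + outer(lab_mult - 1, labour_cost[-1])
    cost[, 1] <- spec$cost_schedule[1] * inv_mult
    ncf <- rev - cost
    dncf <- sweep(ncf, 2, disc, `*`)
    cum <- t(apply(dncf, 1, cumsum))
    first_pos <- apply(cum > 1e-9, 1, function(z)
      if (any(z)) which(z)[1] - 1L else years - 1L)
    vals <- cbind(npv = rowSums(dncf),
                  payback = first_pos,
                  food = rowSums(food) / years,
                  labour = mean(spec$labour_schedule) * lab_mult,
                  investment = spec$cost_schedule[1] * inv_mult)
    mu[lu, ] <- colMeans(vals)
    sd[lu, ] <- apply(vals, 2, stats::sd)
    if (n_reps == 1) sd[lu, ] <- 0
  }
  out <- indicator_table(mu, sd)
  out$n_reps <- n_reps
  class(out) <- c("mc_result", class(out))
  out
}
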