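#' Generate an emulated historical commodity series
#'
#' Produces an annual series of positive values, lognormal around a linear
#' (geometric) trend, standing in for national historical yield and price
#' records. Only the relative, detrended deviations of such a series are used
#' by the Monte-Carlo layer.
#'
#' @param name Commodity label, e.g. \code{"maize_price"}.
#' @param n_years Series length (default 20 annual observations).
#' @param cv Target coefficient of variation of the detrended series.
#' @param trend Relative drift per year.
#' @param level Series level in year 1 (units are irrelevant downstream).
#' @param seed Integer seed.
#' @param kind \code{"yield"} or \code{"price"}.
#' @return Object of class \code{lu_history} with fields \code{name},
#'   \code{values}, \code{kind}.
#' @export
make_history <- function(name, n_years = 20, cv = 0.1, trend = 0, level = 1,
                         seed = 1, kind = c("yield", "price")) {
  kind <- match.arg(kind)
  if (!is.numeric(n_years) || n_years < 2) stop("n_years must be at least 2")
  if (cv < 0) stop("cv must be non-negative")
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  noise <- exp(stats::rnorm(n_years, -sdlog^2 / 2, sdlog))
  values <- level * (1 + trend)^(0:(n_years - 1)) * noise
  structure(list(name = name, values = values, kind = kind),
            class = "lu_history")
}

#' Relative deviations of a historical series
#'
#' Removes a log-linear trend and rescales so the deviations average one;
#' these multiplicative factors form the bootstrap pool for the Monte-Carlo
#' yield and price draws.
#'
#' @param history An \code{lu_history}.
#' @return Numeric vector of multiplicative deviations with mean 1.
#' @export
relative_deviations <- function(history) {
  v <- history$values
  stopifnot(all(v > 0), length(v) >= 2)
  yr <- seq_along(v)
  dev <- unname(exp(stats::residuals(stats::lm(log(v) ~ yr))))
  dev <- dev / mean(dev)
  # a dispersion-free series leaves only floating-point residue: snap it
  if (all(abs(dev - 1) < 1e-9)) dev[] <- 1
  dev
}

# Default parameter set for the study fixture. Absolute cost and yield
# levels are the package's own calibration: they reproduce the qualitative
# indicator orderings of the reference coefficient table (maize the top food
# producer, plantation paying back only at final harvest, forest all-zero),
# not its exact values.
default_fixture_params <- function() {
  list(
    horizon = 20, discount_rate = 0.05, wage = 17.33,
    mortality = 0.005, clear_radius = 1, clearing_cost = 300,
    crop_yield_factor = 1, agroforestry_investment_factor = 1,
    # annual crops
    rice_yield = 3148, rice_price = 0.45,
    rice_inputs_annual = 250, rice_inputs_year0 = 345, rice_labour = 32,
    maize_yield = 3083, maize_price = 0.50,
    maize_inputs_annual = 450, maize_inputs_year0 = 919, maize_labour = 22,
    # cattle (ceba: buy, fatten one season, sell)
    stocking_base = 2, beef_gain = 160, beef_price = 1.85,
    cattle_cost_per_cow = 387, pasture_establishment = 220,
    pasture_inputs_annual = 50, pasture_labour = 8,
    # teak plantation
    teak_density = 1110, teak_thin_years = c(4, 10),
    teak_thin_fractions = c(0.6, 0.5),
    teak_vol_thin = c(0.008, 0.07), teak_vol_harvest = 0.62,
    teak_price = 180, teak_seedling_cost = 0.8,
    teak_establishment_inputs = 476, teak_inputs_annual = 30,
    # alley cropping (teak rows + maize alleys)
    alley_density = 555, alley_thin_years = c(5, 10),
    alley_thin_fractions = c(0.5, 0.5),
    alley_vol_thin = c(0.015, 0.09), alley_vol_harvest = 0.55,
    alley_guard_cost = 150, alley_tree_inputs_annual = 20,
    alley_crop_full_years = c(0, 1, 2), alley_crop_half_years = c(6, 11),
    alley_crop_half_factor = 0.5,
    # silvopasture (cedar over pasture)
    silvo_density = 200, silvo_vol_harvest = 0.35, cedar_price = 180,
    silvo_pasture_area = 0.95, silvo_canopy_end = 0.36,
    silvo_canopy_yield_factor = 0.5,
    silvo_seedling_cost = 0.7, silvo_guard_cost = 60,
    silvo_pest_inputs = 20, silvo_prune_inputs = 10,
    # dietary energy, Mcal per kg
    energy_rice = 2.0, energy_maize = 3.2, energy_beef = 2.9,
    # emulated historical series: cv and trend per commodity
    history_years = 20,
    history_cv = c(rice_yield = 0.18, rice_price = 0.10,
                   maize_yield = 0.25, maize_price = 0.20,
                   beef_yield = 0.02, beef_price = 0.02,
                   teak_price = 0.22, cedar_price = 0.15),
    history_trend = c(rice_yield = 0.005, rice_price = 0.01,
                      maize_yield = 0.005, maize_price = 0.01,
                      beef_yield = 0, beef_price = 0.005,
                      teak_price = 0.015, cedar_price = 0.01)
  )
}

# labour schedules (days/ha/yr, years 0..T) per land use
labour_schedules <- function(p) {
  T1 <- p$horizon + 1
  teak <- rep(12, T1); teak[1] <- 30
  teak[c(1, 2, 4) + 1] <- teak[c(1, 2, 4) + 1] + 10     # pruning
  teak[p$teak_thin_years + 1] <- teak[p$teak_thin_years + 1] + 4
  teak[T1] <- 30                                         # harvest
  alley <- rep(8, T1); alley[1] <- 25
  alley[c(1, 2) + 1] <- 15                               # maize + young trees
  alley[p$alley_thin_years + 1] <- alley[p$alley_thin_years + 1] + 4
  alley[p$alley_crop_half_years + 1] <- alley[p$alley_crop_half_years + 1] + 8
  alley[T1] <- 25
  silvo <- rep(13, T1); silvo[1] <- 20
  silvo[1:3 + 1] <- 15                                   # pest management
  silvo[4:7 + 1] <- 15                                   # pruning
  silvo[T1] <- 20
  list(rice = rep(p$rice_labour, T1), maize = rep(p$maize_labour, T1),
       pasture = rep(p$pasture_labour, T1), teak_plantation = teak,
       alley_cropping = alley, silvopasture = silvo, forest = rep(0, T1))
}

# build one landuse_spec
new_landuse_spec <- function(name, landcover_class, quantities, labour,
                             inputs, wage, investment_components,
                             tree_system = NULL, shading = NULL) {
  cost <- inputs + labour * wage
  stopifnot(abs(sum(investment_components) - cost[1]) < 0.5)
  structure(list(name = name, landcover_class = landcover_class,
                 quantities = quantities, labour_schedule = labour,
                 input_schedule = inputs, cost_schedule = cost,
                 investment_components = investment_components,
                 tree_system = tree_system, shading = shading),
            class = "landuse_spec")
}

# timber quantity schedule (m3/ha/yr) implied by a tree system and per-stem
# merchantable volumes at each thinning and at final harvest
timber_quantities <- function(system, vol_thin, vol_harvest, horizon) {
  q <- rep(0, horizon + 1)
  th <- system$thinnings
  if (!is.null(th) && nrow(th)) for (j in seq_len(nrow(th))) {
    pre <- system$initial_density *
      (1 - system$mortality)^th$year[j] *
      (if (j > 1) prod(1 - th$fraction[seq_len(j - 1)]) else 1)
    q[th$year[j] + 1] <- pre * th$fraction[j] * vol_thin[j]
  }
  q[system$harvest_year + 1] <-
    stem_count(system, system$harvest_year, include_mortality = TRUE) *
    vol_harvest
  q
}

build_fixture <- function(params, seed) {
  p <- params
  T1 <- p$horizon + 1
  lab <- labour_schedules(p)
  zero <- rep(0, T1)

  # emulated national historical series, one sub-seed per commodity series
  set.seed(as.integer(seed))
  sub <- sample.int(1e6, length(p$history_cv))
  histories <- stats::setNames(vector("list", length(p$history_cv)),
                               names(p$history_cv))
  for (k in seq_along(p$history_cv)) {
    nm <- names(p$history_cv)[k]
    histories[[nm]] <- make_history(
      nm, n_years = p$history_years, cv = p$history_cv[[nm]],
      trend = p$history_trend[[nm]], seed = sub[k],
      kind = if (grepl("_price$", nm)) "price" else "yield")
  }

  prices <- c(rice = p$rice_price, maize = p$maize_price,
              beef = p$beef_price, teak = p$teak_price,
              cedar = p$cedar_price)
  energy <- c(rice = p$energy_rice, maize = p$energy_maize,
              beef = p$energy_beef)

  specs <- list()

  ## rice: annual crop, sold from year 0 onwards
  q <- rep(p$rice_yield * p$crop_yield_factor, T1)
  inputs <- rep(p$rice_inputs_annual, T1)
  inputs[1] <- p$clearing_cost + p$rice_inputs_year0
  specs$rice <- new_landuse_spec(
    "rice", "productive", list(rice = q), lab$rice, inputs, p$wage,
    c(clearing = p$clearing_cost, inputs = p$rice_inputs_year0,
      labour = p$rice_labour * p$wage))

  ## maize
  q <- rep(p$maize_yield * p$crop_yield_factor, T1)
  inputs <- rep(p$maize_inputs_annual, T1)
  inputs[1] <- p$clearing_cost + p$maize_inputs_year0
  specs$maize <- new_landuse_spec(
    "maize", "productive", list(maize = q), lab$maize, inputs, p$wage,
    c(clearing = p$clearing_cost, inputs = p$maize_inputs_year0,
      labour = p$maize_labour * p$wage))

  ## pasture: ceba cycle, first sale in year 1
  q <- rep(p$stocking_base * p$beef_gain, T1); q[1] <- 0
  inputs <- rep(p$pasture_inputs_annual, T1)
  cattle <- p$stocking_base * p$cattle_cost_per_cow
  inputs[1] <- p$clearing_cost + p$pasture_establishment + cattle
  specs$pasture <- new_landuse_spec(
    "pasture", "productive", list(beef = q), lab$pasture, inputs, p$wage,
    c(clearing = p$clearing_cost, establishment = p$pasture_establishment,
      cattle = cattle, labour = p$pasture_labour * p$wage))

  ## teak plantation
  sys <- tree_system(p$teak_density, p$teak_thin_years, p$teak_thin_fractions,
                     p$mortality, p$horizon)
  q <- timber_quantities(sys, p$teak_vol_thin, p$teak_vol_harvest, p$horizon)
  seedlings <- p$teak_density * p$teak_seedling_cost
  inputs <- rep(p$teak_inputs_annual, T1)
  inputs[1] <- p$clearing_cost + seedlings + p$teak_establishment_inputs
  specs$teak_plantation <- new_landuse_spec(
    "teak_plantation", "productive", list(teak = q), lab$teak_plantation,
    inputs, p$wage,
    c(clearing = p$clearing_cost, seedlings = seedlings,
      establishment = p$teak_establishment_inputs,
      labour = lab$teak_plantation[1] * p$wage),
    tree_system = sys)

  ## alley cropping: teak rows, maize in the alleys while light allows
  sys <- tree_system(p$alley_density, p$alley_thin_years,
                     p$alley_thin_fractions, p$mortality, p$horizon)
  area <- cultivable_area_fraction(p$alley_density, p$clear_radius)
  crop_factor <- rep(0, T1)
  crop_factor[p$alley_crop_full_years + 1] <- 1
  crop_factor[p$alley_crop_half_years + 1] <- p$alley_crop_half_factor
  qmaize <- p$maize_yield * p$crop_yield_factor * area * crop_factor
  qteak <- timber_quantities(sys, p$alley_vol_thin, p$alley_vol_harvest,
                             p$horizon)
  seedlings <- p$alley_density * p$teak_seedling_cost
  maize_inputs <- p$maize_inputs_annual * area * crop_factor
  inputs <- maize_inputs + p$alley_tree_inputs_annual
  afac <- p$agroforestry_investment_factor
  comp <- afac * c(clearing = p$clearing_cost, seedlings = seedlings,
                   tree_guards = p$alley_guard_cost,
                   crop_inputs = maize_inputs[1],
                   labour = lab$alley_cropping[1] * p$wage)
  inputs[1] <- sum(comp) - comp[["labour"]]
  lab$alley_cropping[1] <- lab$alley_cropping[1] * afac
  shading <- list(crop_area_fraction = area,
                  crop_years = crop_factor)
  specs$alley_cropping <- new_landuse_spec(
    "alley_cropping", "compromise", list(maize = qmaize, teak = qteak),
    lab$alley_cropping, inputs, p$wage, comp,
    tree_system = sys, shading = shading)

  ## silvopasture: cedar over pasture, stocking declines with canopy
  sys <- tree_system(p$silvo_density, mortality = p$mortality,
                     harvest_year = p$horizon,
                     canopy_fraction_schedule =
                       p$silvo_canopy_end * (0:p$horizon) / p$horizon)
  A0 <- p$silvo_pasture_area
  S0 <- p$stocking_base * A0
  canopy <- sys$canopy_fraction_schedule
  stock <- vapply(seq_len(T1), function(k)
    stocking_rate(S0, A0, A0 * (1 - canopy[k]), A0 * canopy[k]), numeric(1))
  qbeef <- stock * p$beef_gain; qbeef[1] <- 0
  qcedar <- timber_quantities(sys, numeric(), p$silvo_vol_harvest, p$horizon)
  seedlings <- p$silvo_density * p$silvo_seedling_cost
  cattle <- S0 * p$cattle_cost_per_cow
  inputs <- rep(p$pasture_inputs_annual * A0, T1)
  inputs[1:3 + 1] <- inputs[1:3 + 1] + p$silvo_pest_inputs
  inputs[4:7 + 1] <- inputs[4:7 + 1] + p$silvo_prune_inputs
  comp <- afac * c(clearing = p$clearing_cost,
                   establishment = p$pasture_establishment * A0,
                   cattle = cattle, seedlings = seedlings,
                   tree_guards = p$silvo_guard_cost,
                   labour = lab$silvopasture[1] * p$wage)
  inputs[1] <- sum(comp) - comp[["labour"]]
  lab$silvopasture[1] <- lab$silvopasture[1] * afac
  shading <- list(pasture_area_fraction = A0,
                  pasture_canopy_yield_factor = p$silvo_canopy_yield_factor,
                  stocking_path = stock)
  specs$silvopasture <- new_landuse_spec(
    "silvopasture", "compromise", list(beef = qbeef, cedar = qcedar),
    lab$silvopasture, inputs, p$wage, comp,
    tree_system = sys, shading = shading)

  ## natural forest: protective, no active management
  specs$forest <- new_landuse_spec(
    "forest", "protective", list(), lab$forest, zero, p$wage,
    c(none = 0))

  structure(list(params = params, seed = seed,
                 horizon = p$horizon, discount_rate = p$discount_rate,
                 wage = p$wage, prices = prices, energy_factors = energy,
                 histories = histories, land_uses = specs),
            class = "study_fixture")
}

#' Build the default study fixture
#'
#' Returns the fully parameterised seven-land-use fixture: per-year cost,
#' labour and yield schedules over the 20-year horizon, tree systems
#' matching the planting and thinning regimes (1110/555/200 stems per ha;
#' plantation thinned 60% in year 4 and 50% in year 10, alley cropping 50%
#' in years 5 and 10, silvopasture unthinned), a daily wage of $17.33, a 5%
#' discount rate, emulated 20-year historical yield/price series, and
#' dietary-energy conversion factors. The same seed always yields an
#' identical fixture.
#'
#' @param seed Integer seed for the emulated historical series.
#' @return Object of class \code{study_fixture}.
#' @export
#' @examples
#' fx <- make_default_fixture(seed = 1)
#' fx$land_uses$teak_plantation$tree_system$initial_density  # 1110
make_default_fixture <- function(seed = 1) {
  build_fixture(default_fixture_params(), seed)
}

#' Perturb a fixture, ceteris paribus
#'
#' Returns a new fixture that differs from the input only in the named
#' parameters; every override key must name an existing fixture parameter.
#' The original fixture is not modified and its historical series are
#' regenerated from the same seed, so everything not named stays identical.
#'
#' @param fixture A \code{study_fixture}.
#' @param overrides Named list of parameter replacements, e.g.
#'   \code{list(teak_price = 234)} or \code{list(crop_yield_factor = 0.6)}.
#' @return A new \code{study_fixture}.
#' @export
perturb_fixture <- function(fixture, overrides = list()) {
  stopifnot(inherits(fixture, "study_fixture"))
  if (!length(overrides)) return(build_fixture(fixture$params, fixture$seed))
  unknown <- setdiff(names(overrides), names(fixture$params))
  if (length(unknown))
    stop("unknown fixture parameter(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(fixture$params, overrides)
  build_fixture(params, fixture$seed)
}

#' @export
print.study_fixture <- function(x, ...) {
  cat("Study fixture:", length(x$land_uses), "land uses, horizon",
      x$horizon, "years, discount rate", x$discount_rate,
      ", wage", x$wage, "$/day\n")
  cat("Land uses:", paste(names(x$land_uses), collapse = ", "), "\n")
  cat("Historical series:", paste(names(x$histories), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a fixture parameter file
#'
#' The fixture is fully determined by its parameter list and seed; both are
#' serialised to a YAML config so runs can be audited and reproduced.
#'
#' @param fixture A \code{study_fixture}.
#' @param path File path.
#' @return \code{read_fixture_config} returns a rebuilt \code{study_fixture}.
#' @export
write_fixture_config <- function(fixture, path) {
  stopifnot(inherits(fixture, "study_fixture"))
  pr <- fixture$params
  # yaml drops names on atomic vectors; keep the per-commodity maps as maps
  pr$history_cv <- as.list(pr$history_cv)
  pr$history_trend <- as.list(pr$history_trend)
  yaml::write_yaml(list(seed = fixture$seed, params = pr), path)
  invisible(path)
}

#' @rdname write_fixture_config
#' @export
read_fixture_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_fixture_params()
  params <- utils::modifyList(defaults, cfg$params)
  # yaml drops names on the cv/trend vectors' structure; restore from lists
  for (f in c("history_cv", "history_trend"))
    params[[f]] <- unlist(cfg$params[[f]])
  build_fixture(params, cfg$seed)
}
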