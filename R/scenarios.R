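#' Weight vector prioritising one objective
#'
#' All indicators keep weight 1 except the named one, which receives
#' \code{factor} (2 = "twice as important").
#'
#' @param indicator Indicator name (see [lu_indicators()]).
#' @param factor Positive weight for the prioritised indicator.
#' @param indicators Indicator set (defaults to the standard five).
#' @return Named weight vector usable as the \code{weights} argument of
#'   [optimize_portfolio()].
#' @export
#' @examples
#' prioritize_objective("npv", 2)
prioritize_objective <- function(indicator, factor = 2,
                                 indicators = lu_indicators()$indicator) {
  if (!indicator %in% indicators)
    stop("unknown indicator '", indicator, "'")
  if (factor <= 0) stop("factor must be positive")
  w <- stats::setNames(rep(1, length(indicators)), indicators)
  w[indicator] <- factor
  w
}

agroforestry_uses <- c("alley_cropping", "silvopasture")

share_row <- function(portfolio, land_uses) {
  s <- stats::setNames(rep(NA_real_, length(land_uses)), land_uses)
  if (!is.null(portfolio)) s[names(portfolio$shares)] <- portfolio$shares
  s
}

#' Sweep a labour or investment constraint
#'
#' Re-optimises the portfolio for each cap value on the portfolio's expected
#' labour demand (days/ha/yr) or investment costs ($/ha). Caps below the
#' minimum attainable level are flagged infeasible rather than aborting the
#' sweep. Also reports the largest cap at which no agroforestry (alley
#' cropping + silvopasture) is selected.
#'
#' @param table An [indicator_table].
#' @param kind \code{"labour"} or \code{"investment"}.
#' @param grid Ordered vector of cap values.
#' @param m Uncertainty multiple.
#' @param weights Optional indicator weights.
#' @return Object of class \code{lu_sweep}: a data frame with one row per
#'   cap (shares, beta, feasibility, agroforestry share) and attributes
#'   \code{portfolios} and \code{agroforestry_free_cap}.
#' @export
sweep_constraint <- function(table, kind = c("labour", "investment"),
                             grid, m = 3, weights = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(grid) >= 1, all(diff(grid) != 0))
  ports <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    pf <- tryCatch(
      if (kind == "labour")
        optimize_portfolio(table, m = m, weights = weights,
                           labour_cap = grid[k])
      else
        optimize_portfolio(table, m = m, weights = weights,
                           investment_cap = grid[k]),
      lu_infeasible = function(e) NULL)
    ports[[k]] <- pf
    sh <- share_row(pf, table$land_uses)
    agro <- sum(sh[intersect(agroforestry_uses, table$land_uses)])
    rows[[k]] <- data.frame(step = grid[k], feasible = !is.null(pf),
                            beta = if (is.null(pf)) NA_real_ else pf$beta,
                            agroforestry = agro,
                            t(sh), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  zero <- out$feasible & !is.na(out$agroforestry) & out$agroforestry < 1e-6
  attr(out, "agroforestry_free_cap") <-
    if (any(zero)) max(out$step[zero]) else NA_real_
  attr(out, "portfolios") <- ports
  attr(out, "kind") <- kind
  class(out) <- c("lu_sweep", class(out))
  out
}

#' Specification of a ceteris-paribus parameter sweep
#'
#' @param parameter One of \code{"crop_yields"},
#'   \code{"agroforestry_investment"}, \code{"teak_price"},
#'   \code{"cedar_price"}, \code{"timber_price"}.
#' @param grid Ordered relative steps, e.g. \code{seq(-1, 1, 0.1)} for
#'   -100% to +100% in 10% increments.
#' @param m Uncertainty multiple for the re-optimisation.
#' @param n_reps Monte-Carlo repetitions per step.
#' @param seed Base seed; each step derives its own sub-seed.
#' @return A list of class \code{sweep_spec}.
#' @export
sweep_spec <- function(parameter = c("crop_yields", "agroforestry_investment",
                                     "teak_price", "cedar_price",
                                     "timber_price"),
                       grid = seq(-1, 1, 0.1), m = 3, n_reps = 10000,
                       seed = 1) {
  parameter <- match.arg(parameter)
  stopifnot(length(grid) >= 1, all(diff(grid) > 0) || all(diff(grid) < 0) ||
              length(grid) == 1)
  structure(list(parameter = parameter, grid = grid, m = m,
                 n_reps = n_reps, seed = as.integer(seed)),
            class = "sweep_spec")
}

# overrides implementing one relative step of a named sweep parameter
sweep_overrides <- function(fixture, parameter, step) {
  p <- fixture$params
  switch(parameter,
    crop_yields = list(crop_yield_factor = p$crop_yield_factor * (1 + step)),
    agroforestry_investment =
      list(agroforestry_investment_factor =
             p$agroforestry_investment_factor * (1 + step)),
    teak_price = list(teak_price = p$teak_price * (1 + step)),
    cedar_price = list(cedar_price = p$cedar_price * (1 + step)),
    timber_price = list(teak_price = p$teak_price * (1 + step),
                        cedar_price = p$cedar_price * (1 + step)),
    stop("unknown sweep parameter '", parameter, "'"))
}

#' Ceteris-paribus parameter sweep
#'
#' For each grid step: perturb the fixture in the single named parameter,
#' re-run the Monte-Carlo simulation (with a step-derived seed) and
#' re-optimise the portfolio. Tracks the share of each agroforestry system
#' across the sweep.
#'
#' @param fixture A \code{study_fixture}.
#' @param spec A [sweep_spec()].
#' @return An \code{lu_sweep} data frame (one row per step) with attribute
#'   \code{portfolios}.
#' @export
sweep_parameter <- function(fixture, spec) {
  stopifnot(inherits(fixture, "study_fixture"), inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$grid))
  ports <- vector("list", length(spec$grid))
  for (k in seq_along(spec$grid)) {
    step <- spec$grid[k]
    fx <- perturb_fixture(fixture, sweep_overrides(fixture, spec$parameter,
                                                   step))
    step_seed <- (spec$seed + 7919L * k) %% .Machine$integer.max
    tab <- simulate_indicators(fx, n_reps = spec$n_reps, seed = step_seed)
    pf <- optimize_portfolio(tab, m = spec$m)
    ports[[k]] <- pf
    sh <- share_row(pf, tab$land_uses)
    rows[[k]] <- data.frame(
      step = step, beta = pf$beta,
      agroforestry = sum(sh[agroforestry_uses]),
      alley_cropping_share = sh[["alley_cropping"]],
      silvopasture_share = sh[["silvopasture"]],
      t(sh), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "portfolios") <- ports
  attr(out, "spec") <- spec
  class(out) <- c("lu_sweep", class(out))
  out
}

#' @export
plot.lu_sweep <- function(x, ...) {
  cols <- intersect(c("alley_cropping_share", "silvopasture_share",
                      "agroforestry"), names(x))
  graphics::matplot(x$step, as.matrix(x[, cols, drop = FALSE]), type = "b",
                    pch = 1, lty = 1, xlab = "step", ylab = "share", ...)
  graphics::legend("topleft", legend = cols, col = seq_along(cols), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Append a stated land-use preference indicator
#'
#' Adds farmers' stated preference scores as a sixth, "more is better"
#' indicator to a coefficient table. The shipped synthetic default scores
#' rank pasture and silvopasture highest.
#'
#' @param table An [indicator_table].
#' @param scores Named preference score per land use.
#' @param sd Named (or scalar) score standard deviations (default 0).
#' @param name Name of the appended indicator.
#' @return An [indicator_table] with one additional column.
#' @export
add_preference_indicator <- function(table, scores, sd = 0,
                                     name = "preference") {
  stopifnot(inherits(table, "indicator_table"))
  missing_lu <- setdiff(table$land_uses, names(scores))
  if (length(missing_lu))
    stop("missing preference score for: ", paste(missing_lu, collapse = ", "))
  scores <- scores[table$land_uses]
  if (length(sd) == 1) sd <- stats::setNames(rep(sd, length(scores)),
                                             names(scores))
  sd <- sd[table$land_uses]
  mean2 <- cbind(table$mean, scores)
  sd2 <- cbind(table$sd, sd)
  colnames(mean2)[ncol(mean2)] <- colnames(sd2)[ncol(sd2)] <- name
  dirs <- c(table$directions, stats::setNames("more", name))
  indicator_table(mean2, sd2, directions = dirs)
}

#' Synthetic land-use preference scores
#'
#' Stand-in preference scores (0-100 scale) ranking pasture and silvopasture
#' highest, consistent with cattle-oriented farmer preferences; the surveyed
#' scores underlying the original analysis are not published, so these are
#' synthetic values.
#'
#' @return Named numeric vector per land use.
#' @export
preference_scores <- function() {
  c(rice = 55, maize = 60, pasture = 80, teak_plantation = 35,
    alley_cropping = 45, silvopasture = 85, forest = 50)
}

#' Workers needed to supply a per-hectare labour rate
#'
#' @param area Farm area (ha).
#' @param labour_rate Labour demand (days/ha/yr).
#' @param working_days_per_year Working days one worker supplies per year
#'   (default 300).
#' @return Number of workers, reported to one decimal.
#' @export
#' @examples
#' workers_required(50, 14)  # 2.3
workers_required <- function(area, labour_rate, working_days_per_year = 300) {
  stopifnot(area > 0, labour_rate > 0, working_days_per_year > 0)
  round(area * labour_rate / working_days_per_year, 1)
}
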