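#' Unfavourable (worst-case) coefficient at uncertainty level m
#'
#' Shifts a coefficient by \code{m} standard deviations in the unfavourable
#' direction: downwards for "more is better" indicators, upwards for
#' "less is better" ones.
#'
#' @param y Predicted (mean) coefficient.
#' @param sd Standard deviation (non-negative).
#' @param m Uncertainty multiple (non-negative).
#' @param direction \code{"more"} or \code{"less"}.
#' @return The worst-case coefficient.
#' @export
#' @examples
#' worst_case_coefficient(8066, 2643, 3, "more")  # 137
worst_case_coefficient <- function(y, sd, m, direction = c("more", "less")) {
  direction <- match.arg(direction)
  stopifnot(all(sd >= 0), m >= 0)
  if (direction == "more") y - m * sd else y + m * sd
}

#' Enumerate uncertainty scenarios
#'
#' For one indicator, an uncertainty scenario assigns each land use either its
#' predicted or its worst-case coefficient. All \code{2^L} subsets of land
#' uses at worst case are enumerated.
#'
#' @param L Number of land uses (at most 20 — the scenario count grows as
#'   \code{2^L}).
#' @return A logical matrix with \code{2^L} rows; \code{TRUE} marks a land use
#'   taking its worst-case coefficient.
#' @export
enumerate_scenarios <- function(L) {
  stopifnot(L >= 1)
  if (L > 20) stop("refusing to enumerate 2^", L, " scenarios (L > 20)")
  s <- 0:(2^L - 1)
  m <- matrix(FALSE, length(s), L)
  for (l in seq_len(L)) m[, l] <- bitwAnd(s, 2^(l - 1)) > 0
  m
}

#' Normalised distance from a target level
#'
#' Expresses an achieved indicator level as a percentage of the span between
#' the target (aspiration) level and the worst level: 0 means the target is
#' met, 100 means performance equals the worst level. Distances are clipped
#' to \[0, 100\]; a degenerate indicator (target equal to worst) carries no
#' information and gets distance 0.
#'
#' @param achieved Achieved level.
#' @param target Target (best attainable) level.
#' @param worst Worst level defining the normalisation span.
#' @param direction \code{"more"} or \code{"less"}.
#' @return Distance in percent, in \[0, 100\].
#' @export
normalize_distance <- function(achieved, target, worst,
                               direction = c("more", "less")) {
  direction <- match.arg(direction)
  span <- if (direction == "more") target - worst else worst - target
  d <- ifelse(abs(span) < 1e-12, 0,
              if (direction == "more") 100 * (target - achieved) / span
              else 100 * (achieved - target) / span)
  pmin(pmax(d, 0), 100)
}

# Robust LP front-end around boot::simplex (minimisation, x >= 0).
# The underlying routine mishandles <=-constraints with negative right-hand
# sides (they never enter its phase-1 problem) and can terminate at an
# invalid point under its default pivoting tolerance, so: negative-rhs rows
# are rerouted as flipped >=-constraints, solutions are verified against
# every constraint, and a ladder of pivot tolerances is retried before
# giving up.
solve_lp <- function(a, A1, b1, A3, b3) {
  A2 <- NULL; b2 <- NULL
  neg <- b1 < 0
  if (any(neg)) {
    A2 <- -A1[neg, , drop = FALSE]; b2 <- -b1[neg]
    A1 <- A1[!neg, , drop = FALSE]; b1 <- b1[!neg]
  }
  if (!is.null(A1) && nrow(A1) == 0) { A1 <- NULL; b1 <- NULL }
  valid <- function(x) {
    ok <- all(x >= -1e-9) && max(abs(A3 %*% x - b3)) < 1e-6
    if (ok && !is.null(A1)) {
      s <- pmax(1, abs(b1), apply(abs(A1), 1, max))
      ok <- max((A1 %*% x - b1) / s) < 1e-6
    }
    if (ok && !is.null(A2)) {
      s <- pmax(1, abs(b2), apply(abs(A2), 1, max))
      ok <- max((b2 - A2 %*% x) / s) < 1e-6
    }
    ok
  }
  n_iter <- 100 * (length(a) + length(b1) + length(b2) + length(b3))
  saw_infeasible <- FALSE
  for (eps in c(1e-8, 1e-6, 1e-9)) {
    sol <- boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         A3 = A3, b3 = b3, maxi = FALSE,
                         n.iter = n_iter, eps = eps)
    if (sol$solved == -1) { saw_infeasible <- TRUE; next }
    if (sol$solved == 1 && valid(sol$soln))
      return(list(status = "ok", x = sol$soln))
  }
  list(status = if (saw_infeasible) "infeasible" else "failed")
}

# Build the scenario constraint coefficients: one row per (indicator,
# scenario), giving each land use's weighted normalised distance
# contribution. Within each scenario the target is the best and the worst the
# poorest coefficient among land uses, so any portfolio's distance lies in
# [0, 100] by construction.
scenario_constraints <- function(table, m, weights) {
  L <- length(table$land_uses)
  scen <- enumerate_scenarios(L)
  rows <- vector("list", length(table$indicators))
  for (k in seq_along(table$indicators)) {
    i <- table$indicators[k]
    dir <- table$directions[[i]]
    mu <- table$mean[, i]
    wc <- worst_case_coefficient(mu, table$sd[, i], m, dir)
    cc <- matrix(rep(mu, each = nrow(scen)), nrow(scen), L)
    cc[scen] <- matrix(rep(wc, each = nrow(scen)), nrow(scen), L)[scen]
    tgt <- if (dir == "more") apply(cc, 1, max) else apply(cc, 1, min)
    wst <- if (dir == "more") apply(cc, 1, min) else apply(cc, 1, max)
    span <- ifelse(abs(tgt - wst) < 1e-12, NA_real_,
                   if (dir == "more") tgt - wst else wst - tgt)
    d <- if (dir == "more") 100 * (tgt - cc) / span else 100 * (cc - tgt) / span
    d[is.na(d)] <- 0                      # degenerate scenario: no information
    rows[[k]] <- weights[[i]] * d
  }
  D <- do.call(rbind, rows)
  # index of the all-worst-case scenario row within each indicator block
  list(D = D, allworst = seq_along(table$indicators) * nrow(scen))
}

#' Optimise a robust land-use portfolio
#'
#' Solves the robust min-max goal-programming linear program: choose area
#' shares (summing to one) that minimise the worst weighted, normalised
#' shortfall from per-indicator target levels across all uncertainty
#' scenarios. Uncertainty scenarios assign each land use, indicator by
#' indicator, either its predicted coefficient or its coefficient shifted
#' \code{m} standard deviations in the unfavourable direction; within each
#' scenario achievement is normalised between the best (target) and poorest
#' coefficient among the land uses.
#'
#' @param table An [indicator_table], e.g. [baseline_coefficients()] or the
#'   result of [simulate_indicators()].
#' @param m Uncertainty multiple: 0 ignores uncertainty (risk neutral), 1.5
#'   moderate and 3.0 strong risk aversion.
#' @param weights Optional named positive weights per indicator (default all
#'   1); see [prioritize_objective()].
#' @param labour_cap,investment_cap Optional caps on the portfolio's expected
#'   labour demand (days/ha/yr) and investment costs ($/ha), computed from the
#'   predicted coefficients.
#' @param forced_zero Optional character vector of land uses excluded from
#'   the portfolio.
#' @return An object of class \code{lu_portfolio} with components
#'   \code{shares} (named, summing to 1), \code{beta} (optimised worst
#'   distance, percent), \code{achieved} (per indicator: predicted and
#'   guaranteed worst-case portfolio level), and the configuration. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{plot}.
#' @export
#' @examples
#' opt <- optimize_portfolio(baseline_coefficients(), m = 0)
#' round(coef(opt), 3)
optimize_portfolio <- function(table, m = 0, weights = NULL,
                               labour_cap = NULL, investment_cap = NULL,
                               forced_zero = NULL) {
  stopifnot(inherits(table, "indicator_table"), m >= 0)
  L <- length(table$land_uses)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(table$indicators)),
                                                   table$indicators)
  if (is.null(names(weights)) || !all(table$indicators %in% names(weights)))
    stop("weights must be named for every indicator")
  if (any(weights <= 0)) stop("weights must be positive")
  weights <- weights[table$indicators]

  sc <- scenario_constraints(table, m, weights)
  D <- sc$D
  # variables: a_1..a_L, beta;  minimise beta
  A1 <- cbind(D, -1)                        # D a - beta <= 0
  b1 <- rep(0, nrow(A1))
  if (!is.null(labour_cap)) {
    if (!"labour" %in% table$indicators) stop("table has no labour indicator")
    A1 <- rbind(A1, c(table$mean[, "labour"], 0)); b1 <- c(b1, labour_cap)
  }
  if (!is.null(investment_cap)) {
    if (!"investment" %in% table$indicators) stop("table has no investment indicator")
    A1 <- rbind(A1, c(table$mean[, "investment"], 0)); b1 <- c(b1, investment_cap)
  }
  A3 <- matrix(c(rep(1, L), 0), 1)          # shares sum to one
  b3 <- 1
  if (!is.null(forced_zero)) {
    bad <- setdiff(forced_zero, table$land_uses)
    if (length(bad)) stop("unknown land use(s): ", paste(bad, collapse = ", "))
    for (lu in forced_zero) {
      row <- rep(0, L + 1); row[match(lu, table$land_uses)] <- 1
      A3 <- rbind(A3, row); b3 <- c(b3, 0)
    }
  }
  sol <- solve_lp(a = c(rep(0, L), 1), A1 = A1, b1 = b1, A3 = A3, b3 = b3)
  infeasible <- function()
    stop(structure(
      class = c("lu_infeasible", "error", "condition"),
      list(message = "portfolio optimisation is infeasible under the given constraints",
           call = NULL)))
  if (sol$status == "infeasible") infeasible()
  if (sol$status != "ok") stop("LP solver did not converge")
  beta <- sol$x[L + 1]

  # min-max optima are often non-unique (a whole face of the simplex attains
  # beta); refine lexicographically by minimising the summed weighted
  # distance under the all-worst-case scenarios among beta-optimal solutions,
  # which selects a canonical vertex and keeps sweep curves stable
  eps <- 1e-8 * max(1, abs(beta))
  cobj <- colSums(D[sc$allworst, , drop = FALSE])
  nA1 <- nrow(A1)
  A1b <- rbind(D, if (nA1 > nrow(D)) A1[(nrow(D) + 1):nA1, seq_len(L),
                                        drop = FALSE])
  b1b <- c(rep(beta + eps, nrow(D)), if (nA1 > nrow(D)) b1[(nrow(D) + 1):nA1])
  A3b <- A3[, seq_len(L), drop = FALSE]
  sol2 <- solve_lp(a = cobj, A1 = A1b, b1 = b1b, A3 = A3b, b3 = b3)
  if (sol2$status == "ok") {
    shares <- stats::setNames(pmax(sol2$x[seq_len(L)], 0), table$land_uses)
    beta <- max(D %*% sol2$x[seq_len(L)])
  } else {
    shares <- stats::setNames(pmax(sol$x[seq_len(L)], 0), table$land_uses)
  }
  shares <- shares / sum(shares)

  achieved <- t(vapply(table$indicators, function(i) {
    wc <- worst_case_coefficient(table$mean[, i], table$sd[, i], m,
                                 table$directions[[i]])
    c(predicted = sum(shares * table$mean[, i]),
      guaranteed = sum(shares * wc))
  }, numeric(2)))

  structure(
    list(shares = shares, beta = beta, achieved = achieved,
         config = list(m = m, weights = weights, labour_cap = labour_cap,
                       investment_cap = investment_cap,
                       forced_zero = forced_zero),
         table = table),
    class = "lu_portfolio"
  )
}

#' Bray-Curtis dissimilarity between two portfolios
#'
#' Half the sum of absolute differences between two compositional share
#' vectors on the same land-use ordering; 0 for identical portfolios, 1 for
#' disjoint ones.
#'
#' @param p,q Share vectors, each summing to 1.
#' @return Dissimilarity in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(0.6, 0.4, 0), c(0.2, 0.4, 0.4))  # 0.4
bray_curtis <- function(p, q) {
  if (length(p) != length(q)) stop("share vectors differ in length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("share vectors must each sum to 1")
  sum(abs(p - q)) / 2
}
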