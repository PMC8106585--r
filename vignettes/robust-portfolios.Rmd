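---
title: "Robust multi-criteria land-use portfolios with agroportfolio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust multi-criteria land-use portfolios with agroportfolio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroportfolio)
```

## The decision problem

Smallholders at a tropical forest frontier choose how to divide a farm among
land uses — annual crops (rice, maize), cattle pasture, a teak plantation,
two agroforestry systems (alley cropping: teak rows with maize in the
alleys; silvopasture: Spanish cedar planted into grazed pasture) and
unmanaged natural forest. Each land use serves several, partly conflicting,
household goals. `agroportfolio` scores every land use against five
socio-economic indicators and then composes the farm *portfolio* (vector of
area shares summing to one) that minimises the worst normalised shortfall
across all indicators under uncertainty.

The five indicators, with their desirable directions:

| indicator   | units      | direction      | meaning                                    |
|-------------|------------|----------------|--------------------------------------------|
| npv         | \$/ha      | more is better | discounted 20-year profitability (5 %/yr)  |
| payback     | years      | less is better | first year of positive cumulative discounted cash flow |
| food        | Mcal/ha/yr | more is better | mean annual dietary energy produced        |
| labour      | days/ha/yr | less is better | mean annual labour demand                  |
| investment  | \$/ha      | less is better | all costs incurred in year 0               |

## The land-use model

Each land use is a deterministic 21-year (years 0–20) schedule of costs,
labour and physical outputs, built by the fixture generator
(`make_default_fixture()`):

* **Stand dynamics.** Tree systems are planted at 1110 (plantation), 555
  (alley cropping) and 200 (silvopasture) stems/ha. The plantation is
  thinned 60 % in year 4 and 50 % in year 10; alley cropping 50 % in years
  5 and 10; silvopasture is unthinned. Excluding the 0.5 %/yr mortality the
  final stands are 222, 139 and 200 stems/ha (`stem_count()`).
* **Shading rules.** Keeping a 1 m vegetation-free circle around each of
  555 seedlings removes 17 % of the alley-cropping maize area
  (`cultivable_area_fraction()`). Maize is cultivated at full yield in
  years 0–2, at half yield in the two post-thinning years (6 and 11), and
  not at all otherwise. In silvopasture, 5 % of the pasture area is lost to
  tree circles (the model uses the stated 5 % rather than the geometric
  6.3 % — the discrepancy is inherited from the source material) and
  pasture under canopy supports only half the stock: the stocking rate
  follows `stocking_rate()`, declining linearly from 1.9 cows/ha to 1.56 as
  the canopy fraction grows from 0 to 36 % of the initial pasture area over
  the rotation. Only the canopy endpoint is anchored; the linear path
  between 0 and 36 % is a modelling choice.
* **Cattle.** Pasture runs an annual buy–fatten–sell cycle; revenue is
  proportional to the current stocking rate, and the cattle purchase is part
  of the year-0 investment.
* **Cash flow.** `net_cash_flow()` sums quantity × price over commodities
  minus the year's cost; `npv()` discounts at 5 %/yr; `discounted_payback()`
  returns the first year with positive cumulative discounted cash flow.
  Conventions for degenerate series: an all-zero cash flow (natural forest)
  pays back at year 0; a series that never turns positive is assigned the
  final year 20, so a plantation that only pays off at final harvest
  reports a 20-year payback. Paybacks are whole years.

## What the synthetic fixture emulates — and what it does not

The cost tables, yield series and timber-grade schedules underlying the
reference coefficients are not available; the fixture generator emulates
them. Printed anchors (tree densities, thinning regimes, the \$17.33 daily
wage, the 5 % discount rate, the shading rules, the 17 %/5 % area losses)
are reproduced exactly. Absolute cost and yield levels are the package's own
calibration, chosen once so that the deterministic indicators reproduce the
qualitative orderings of the reference coefficient table — maize the top
food producer, rice the most labour-demanding crop, plantation establishment
the most expensive and paying back only at final harvest, pasture the
cheapest-to-run system, forest identically zero. Exact reproduction of the
reference coefficient values is *not* attempted: those coefficients are
shipped verbatim as `baseline_coefficients()` and drive every baseline
optimisation. Consequently, tests that pass on the synthetic fixture show
that the machinery behaves correctly under realistic magnitudes; they do not
validate the original cost data.

Historical variability is emulated by `make_history()`: 20 annual
observations, lognormal around a mild geometric trend, one series per
commodity price/yield, with coefficients of variation chosen per commodity
(volatile maize and timber prices, near-stable beef). Real agricultural
series have autocorrelation and cross-correlation (e.g. yield–price
covariance) that this generator deliberately omits.

## Monte-Carlo layer

`simulate_indicators()` runs the cash-flow model under uncertainty
(10,000 repetitions for production coefficients). Per repetition and year,
yield and price multipliers are resampled i.i.d. from the mean-normalised,
log-linearly detrended deviations of each commodity's historical series;
labour and investment get one multiplier each, drawn from a normal with a
10 % coefficient of variation truncated at zero. Yield and price draws are
independent across commodities and years — a flagged simplification. Means
and standard deviations over repetitions form the coefficient table. With
degenerate inputs (constant histories, zero input CV) every standard
deviation collapses to zero and the means equal the deterministic
evaluation, which the tests assert.

## The robust min-max optimisation

Let $\hat y_{i,l}$ and $SD_{i,l}$ be the mean and standard deviation of
indicator $i$ for land use $l$. At uncertainty level $m$ the worst-case
coefficient is $\hat y_{i,l} \mp m\,SD_{i,l}$, shifted against the
indicator's desirable direction — deviations are always unfavourable. An
*uncertainty scenario* for indicator $i$ assigns each land use either its
predicted or its worst-case coefficient; all $2^L = 128$ subsets are
enumerated per indicator (640 constraints for 5 indicators). The LP is

$$\min_\beta \; \beta \quad \text{s.t.} \quad
w_i\, D_{i,u}(a) \le \beta \;\; \forall i, u, \qquad
\textstyle\sum_l a_l = 1,\; a_l \ge 0,$$

where $D_{i,u}(a)$ is the portfolio's normalised distance from the target
within scenario $u$, plus optional linear caps on the portfolio's expected
labour demand and investment cost.

**Normalisation convention.** Within each scenario the target $T_{i,u}$ is
the best and the worst level $W_{i,u}$ the poorest coefficient among the
land uses, and $D = 100\,(T - \text{achieved})/(T - W)$ (direction
reversed for less-is-better indicators). Because achievement is a convex
combination of coefficients inside the scenario, distances stay in
$[0, 100]$ by construction; reported distances are additionally clipped so a
degenerate indicator (all coefficients equal) carries no information. The
original formulation's exact normalisation is not available. The package's
per-scenario convention was selected at design time as the variant of the
goal-programming family that best reproduces the reference baseline
portfolio compositions across all three uncertainty levels; global-range
alternatives (targets at predicted values, worsts at level-$m$ values)
reproduce the risk-neutral solution but diverge at $m > 0$. Share tolerances
of a few percentage points in the tests absorb the remaining convention
uncertainty; one reference share (maize at $m = 1.5$) deviates by ~5 points
under every convention examined.

**Uniqueness.** Min-max optima frequently lie on a face of the simplex, not
a single vertex. Among $\beta$-optimal solutions the package selects the one
minimising the summed weighted distance under the all-worst-case scenarios
(a second, lexicographic LP stage with an $10^{-8}$-scaled slack on
$\beta$). This makes reported portfolios canonical and keeps sweep curves
stable where vertices would otherwise flip between near-ties.

**Numerics.** The LP back-end is the two-phase simplex in `boot`. Two of
its edge cases are handled defensively: constraints with negative
right-hand sides are rerouted as flipped $\ge$-constraints so they enter
the phase-1 problem, every returned solution is verified against all
constraints, and a ladder of pivot tolerances ($10^{-8}$, $10^{-6}$,
$10^{-9}$) is retried before an instance is declared infeasible or failed.

```{r}
tab <- baseline_coefficients()
optimize_portfolio(tab, m = 0)
```

## Scenario engine

* `prioritize_objective("npv", 2)` doubles one indicator's weight; weights
  multiply distances ($w_i D \le \beta$), so "twice as important" is
  $w = 2$. This is a declared convention — the original weighting procedure
  is not available.
* `sweep_constraint()` re-optimises along a grid of labour or investment
  caps, flags infeasible caps, and reports the largest cap at which no
  agroforestry is selected.
* `sweep_parameter()` implements the ceteris-paribus sweeps: per grid step
  it perturbs exactly one fixture parameter, re-simulates with a
  step-derived seed (steps are independent yet the whole curve is
  reproducible from the base seed) and re-optimises. The "agroforestry
  subsidy" sweep scales the entire year-0 establishment outlay of the two
  agroforestry systems proportionally — the reference sweep varies total
  investment costs; handing out free seedlings and tree guards corresponds
  to one point of that sweep (roughly a 13–20 % reduction), not to the
  sweep itself.
* `add_preference_indicator()` appends stated land-use preferences as a
  sixth, more-is-better indicator. The shipped `preference_scores()` are
  synthetic (the surveyed scores are not available), ranking silvopasture and
  pasture highest to represent cattle-oriented cultural preferences.
* `workers_required()` converts a per-hectare labour rate to worker
  equivalents at 300 working days per worker-year; 300 is the package's
  assumption, chosen because it reproduces the reference example of 2.3
  workers for a 50 ha farm at 14 days/ha/yr.

## Problem sizes and tolerances used by the test suite

The shipped tests run the Monte-Carlo layer at 10,000 repetitions where a
coefficient of variation or a sweep direction is asserted, and at 200–300
repetitions where only reproducibility or plumbing is exercised. Sweep
directions at $m = 3$ are asserted as near-monotonicity with a 5-point
share allowance: with finite repetitions and lexicographic tie-breaking,
adjacent steps can still swap near-tied vertices by a few points without
contradicting the underlying direction. The LP is cross-checked against an
independent exhaustive grid search (1 % share resolution) on every
3-land-use subtable of the packaged coefficients.

## Known limitations

* Static model: no soil-fertility decay, no option value of delaying
  harvest, no staggered tree establishment.
* Not spatially explicit; site conditions are homogeneous.
* Yield–price covariance and serial correlation are not modelled.
* The synthetic fixture's absolute levels are calibrated stand-ins; sweep
  *levels* (e.g. the share reached at a given subsidy) are fixture-dependent
  even where sweep *directions* are robust.
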