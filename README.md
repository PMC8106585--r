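# agroportfolio

Robust multi-criteria optimisation of agroforestry land-use portfolios.

## What it does and for whom

Researchers and policy analysts evaluating agroforestry at tropical forest
frontiers need to know under which socio-economic conditions farmers would
plausibly adopt it. `agroportfolio` implements a three-stage analysis for a
seven-land-use farming system (rice, maize, cattle pasture, teak plantation,
alley cropping, silvopasture, natural forest):

1. **Land-use model.** A 20-year capital-budgeting model with Monte-Carlo
   uncertainty scores every land use against five indicators: net present
   value (\$/ha, 5 % discount rate), discounted payback period (years),
   food production (Mcal/ha/yr), labour demand (days/ha/yr) and investment
   costs (\$/ha). Yield and price variability is bootstrapped from
   historical relative deviations; labour and investment vary with a 10 %
   coefficient of variation.
2. **Robust min-max optimisation.** With mean `ŷ(i,l)` and standard
   deviation `SD(i,l)` per indicator `i` and land use `l`, worst-case
   coefficients `ŷ ∓ m·SD` (always shifted unfavourably) define, per
   indicator, `2^L` uncertainty scenarios — every subset of land uses at
   worst case. The linear program chooses area shares `a(l) ≥ 0`,
   `Σ a(l) = 1`, minimising `β` subject to `w(i)·D(i,u) ≤ β` for every
   indicator and scenario, where `D` is the portfolio's shortfall from the
   within-scenario target, normalised to 0–100 % of the target–worst span.
   `m = 0, 1.5, 3.0` represent risk-neutral, moderately and strongly
   risk-averse decision-making.
3. **Scenario engine.** Objective re-weighting, labour/investment
   constraint sweeps (optionally with a stated-preference indicator), and
   ceteris-paribus parameter sweeps (crop yields, agroforestry investment
   subsidy, teak/cedar prices) that re-run simulation and optimisation per
   step.

The reference coefficient table ships with the package
(`baseline_coefficients()`); a synthetic fixture generator
(`make_default_fixture()`) emulates the otherwise unavailable cost/yield/price/labour
schedules so the full pipeline is runnable and testable end to end.

## Worked example

```r
library(agroportfolio)

tab <- baseline_coefficients()   # packaged mean ± SD coefficient table
pf  <- optimize_portfolio(tab, m = 0)
summary(pf)
#> Robust land-use portfolio (m = 0 )
#> Worst normalised distance beta: 41.25 %
#> Shares:
#>          maize alley_cropping         forest
#>          0.582          0.032          0.385
#>
#> Achieved indicator levels (portfolio mean / guaranteed worst case):
#>            predicted guaranteed
#> npv          4881.84    4881.84
#> payback         0.84       0.84
#> food         5795.93    5795.93
#> labour         13.20      13.20
#> investment    684.37     684.37
```

A risk-neutral decision-maker allocates 58 % to maize, 3 % to alley
cropping and leaves 39 % as natural forest; the worst indicator sits 41 %
of the way from its target to its worst level (at `m = 0` predicted and
guaranteed levels coincide). Raising `m` diversifies the portfolio:

```r
coef(optimize_portfolio(tab, m = 3))   # teak 8%, silvopasture 22%, ...
```

Scenario analyses follow the same pattern:

```r
# labour cap sweep at high risk aversion
sw <- sweep_constraint(tab, "labour", grid = seq(8, 22, 1), m = 3)
attr(sw, "agroforestry_free_cap")     # 15: below this, no agroforestry
#> [1] 15

# ceteris-paribus subsidy sweep on the synthetic fixture
fx <- make_default_fixture(seed = 1)
sweep_parameter(fx, sweep_spec("agroforestry_investment",
                               grid = seq(-1, 0, 0.1), m = 3,
                               n_reps = 10000, seed = 1))
```

`run_pipeline("config.yaml")` drives simulate → optimise → sweep from a
single YAML config and writes coefficient CSVs, portfolio TSV/JSON files
and a JSON run manifest with seeds and file digests.

## Package layout

- `R/fixtures.R` — synthetic fixture generator, historical-series emulation,
  ceteris-paribus perturbation, YAML serialisation
- `R/landuse.R` — stand dynamics, shading/stocking rules, cash flows, NPV,
  discounted payback, food energy, Monte-Carlo simulation
- `R/optimizer.R` — worst-case coefficients, scenario enumeration,
  normalised distances, the min-max LP, Bray–Curtis dissimilarity
- `R/scenarios.R` — objective prioritisation, constraint and parameter
  sweeps, preference indicator, worker conversion
- `R/io.R` — coefficient-table CSV I/O, portfolio TSV/JSON, pipeline runner
  with manifests
- `vignettes/robust-portfolios.Rmd` — model, conventions, and limitations
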