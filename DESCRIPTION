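Package: agroportfolio
Title: Robust Multi-Criteria Optimisation of Agroforestry Land-Use Portfolios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates land uses at a tropical forest frontier against five
    socio-economic indicators (net present value, discounted payback period,
    food production, labour demand, investment costs) with a Monte-Carlo
    cash-flow model, and composes farm portfolios with a robust min-max
    goal-programming linear program that minimises the worst normalised
    shortfall across indicators under enumerated uncertainty scenarios.
    Includes a scenario engine for objective weighting, labour and
    investment constraints, and ceteris-paribus parameter sweeps, plus a
    synthetic fixture generator emulating the underlying cost, yield, price
    and labour schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
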