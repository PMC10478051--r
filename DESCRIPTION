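Package: foodscape
Title: Longitudinal Food-Environment Equity Analysis on Establishment Registries
Version: 0.1.0
Authors@R: person("Foodscape", "Maintainers", email = "maintainers@foodscape.invalid",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of neighbourhood food environments from
    establishment-level retail registries. Classifies food retail outlets into NAICS-based
    categories and health tiers, aggregates tract-year panels of the modified Retail Food
    Environment Index (mRFEI) and the Herfindahl-Hirschman Index (HHI), detects spatial
    hot and cold spots of food-environment healthiness with the Getis-Ord Gi* statistic,
    and estimates race/ethnicity associations by two-way fixed-effects Poisson
    pseudo-maximum-likelihood with tract-clustered standard errors. Includes a synthetic
    registry generator with known ground truth so the whole pipeline is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
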