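Package: pahrisk
Title: Probabilistic Carcinogenic Risk Assessment of PAHs in Drinking Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for human-health risk assessment of polycyclic aromatic
    hydrocarbons (PAHs) in drinking water: benzo[a]pyrene toxic-equivalency
    (BaPeq) weighting of multi-analyte profiles, screening against national
    drinking-water standards, deterministic chronic-daily-intake and lifetime
    cancer-risk calculation for the ingestion and dermal routes, Monte Carlo
    uncertainty propagation with rank-correlation sensitivity analysis,
    geometric-mean summary tables with season/water-type/group comparisons,
    and a synthetic monitoring-campaign generator emulating a two-season,
    three-water-type village study design with left-censored lognormal
    concentrations and village cancer registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    fitdistrplus,
    nortest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
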