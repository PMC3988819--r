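Package: pterotrend
Title: Time-Calibration, Imputation and Multi-Regime Ornstein-Uhlenbeck
    Modelling of Pterosaur Wingspan Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing body-size macroevolution in fossil clades,
    built around the pterosaur wingspan problem: stochastic time-calibration
    of cladograms against stratigraphic age ranges (minimum-branch-length and
    'equal' methods), phylogenetic generalized least squares imputation of
    missing skeletal elements and wingspans under Pagel's lambda, maximum
    likelihood fitting of Brownian-motion and multi-regime Ornstein-Uhlenbeck
    trait models with per-tip measurement error on non-ultrametric trees,
    AICc model comparison aggregated over replicate calibrations, and
    era-split trend regressions of log wingspan on geological age. Includes
    a synthetic-data generator that emulates the statistical structure of a
    fossil measurement compilation so the full pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
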