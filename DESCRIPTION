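Package: xylemsafety
Title: Xylem Vulnerability Curves, Site Water Availability and Hydraulic
    Trait Variance Partitioning in Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for branch xylem hydraulic safety in
    temperate broadleaf forest stands. Fits the specific-conductivity
    formulation of the sigmoidal (Pammenter-Vander Willigen) vulnerability
    curve to flow-centrifuge (cavitron) series, derives P12/P50/P88 and the
    logit-scale slope with bootstrap confidence bands, computes site water
    availability metrics (climatic water balance; plant-available soil water
    capacity from van Genuchten retention curves via a texture-class
    pedotransfer lookup), tree- and branch-level covariates (Hegyi
    competition index, xylem-area allometry, specific conductivity, branch
    age from ring counts), and partitions trait variance with linear
    mixed-effects models (random site intercepts, Satterthwaite-type Wald t
    tests, Nakagawa marginal and conditional R-squared). A synthetic-study
    generator emulating a 30-site x 10-tree hierarchical design makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    minpack.lm,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
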