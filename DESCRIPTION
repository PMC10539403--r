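Package: fallowland
Title: Abandoned Cropland Detection, Suitability, and Reuse Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cropland abandonment from annual land-cover class
    grids using a temporal-consistency filter and the FAO five-year
    fallow rule, scores abandoned land for recultivation (presence-
    background suitability model with a 0.2 recultivatability cut and
    protected-area masking) and for reforestation via natural regrowth
    (potential-natural-vegetation overlay), computes calorie food-
    production potential and net climate-change-mitigation potential
    (regrowth sequestration credit minus amortized land-clearing
    emissions), and runs land-allocation scenarios that quantify
    trade-offs, synergies, and the benefit of spatial prioritization.
    Includes a synthetic-data generator that emulates the statistical
    structure of the real inputs, stratified map-accuracy assessment
    with error-adjusted area estimation, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
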