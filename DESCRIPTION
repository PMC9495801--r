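Package: bcatea
Title: Flowsheet Simulation and Techno-Economic Analysis of a Microalgal
    Amino-Acid Biofertilizer Plant
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady-state mass and energy balance of a six-stage plant that
    converts microalgal sludge from wastewater treatment into a liquid
    biofertilizer concentrated in free L-amino acids: high-pressure
    homogenization, enzymatic protein hydrolysis with lime/sulfuric-acid pH
    control and gypsum formation, solar-heated hydrolysis, disc-centrifuge
    solid-liquid separation, and storage/packaging.  On top of the flowsheet
    it provides annual production and consumption totals, CAPEX and OPEX
    aggregation, discounted-cash-flow profitability indicators (NPV, IRR,
    discounted payback, profitability index), and a Box-Behnken
    response-surface sensitivity analysis over sludge cost, enzyme cost and
    biofertilizer sale price.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
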