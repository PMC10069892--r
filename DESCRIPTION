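Package: respitraits
Title: Respiratory CO2 Traits in Constraint-Based Plant Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of respiratory CO2 traits in
    compartmentalized plant metabolic models: an SBML (Level 3 + fbc) reader,
    flux balance analysis and parsimonious FBA over a built-in simplex backend,
    per-reaction CO2 production/consumption inventories and cross-model
    comparison of CO2-producing EC-number sets, the Farquhar-von
    Caemmerer-Berry net-assimilation and carbon-use-efficiency trait panel,
    single and double reaction-knockout screens, linear-fractional
    minimization of respiration per unit biomass carbon via the
    Charnes-Cooper transformation, classical growth-and-maintenance
    respiration models, and a synthetic photoautotroph generator with
    analytically known optima for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
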