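Package: acidevolve
Title: In Silico Evolution of Microbial Organic-Acid Production
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constraint-based modelling toolkit for in silico evolution of
    organic-acid fermentation in filamentous fungi. Provides a flux-balance
    analysis core with a built-in bounded-variable simplex solver and
    parsimonious tie-breaking, a two-phase dynamic batch-fermentation
    simulator (phosphate-storage growth followed by proton-production),
    a closed-form productivity fitness function evaluated from phase-2
    flux-balance snapshots, a genetic algorithm that evolves reaction flux
    bounds on a two-chromosome genome, and a downstream analysis pipeline
    (complementation pruning, mutation frequencies, representative
    solutions). Includes SBML model input/output and a deterministic toy
    core-carbon-metabolism generator for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
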