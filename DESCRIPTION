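Package: HotairWnt
Title: Kinetic Modelling of the HOTAIR-Mediated Wnt/beta-Catenin Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic kinetic model of the lncRNA-HOTAIR-mediated
    Wnt/beta-catenin signalling pathway driving MMP-13 expression in
    chondrocytes. Implements the 25-species, 37-reaction mass-action/Hill
    network with its seven conserved moieties, a stiff ODE simulator,
    limit-cycle feature extraction (regime, period, amplitude), local
    scaled sensitivity analysis of all reaction fluxes with respect to all
    42 kinetic parameters, and in-silico perturbation scenarios (HOTAIR
    knockout, 100-fold parameter scans). Includes a YAML configuration
    format, CSV/JSON exports, SBML Level 3 export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, deSolve, yaml, jsonlite, xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
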