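Package: sigcon
Title: Design and Simulation of RNA Signal-Connector Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing trans-acting RNA devices ("signal-connectors")
    that couple a 20-nt antisense targeting domain to ligand- or
    protein-sensing RNA aptamers in order to repress or activate translation
    of a chosen mRNA. Provides a transparent base-pair-maximisation folding
    engine with an exhaustive enumeration oracle, chimera assembly in
    repressor, activator and sequestration-switch topologies, structure-based
    selection (antisense exposedness, aptamer preservation, 5'-distance
    prior), a Hill/Emax model of ligand-dependent translational repression and
    eIF4G-recruitment activation with aptamer-valency saturation,
    dose-response calibration, construction and truth-table simulation of the
    seven basic Boolean logic gates, and ODE models of connector-mediated
    pathway rewiring, feedback loops and cell-state classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
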