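Package: hybridcycle
Title: Hybrid Boolean/Piecewise-Linear Simulation of the Mammalian Cell
    Cycle
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates mammalian cell-cycle progression with a hybrid
    model in which cyclins A, B and E follow piecewise-linear kinetics
    (solved analytically, no numerical integration) while their
    transcription factors and ubiquitin-ligase regulators are Boolean
    switches stepping through a fixed nine-state sequence.  State
    residence times combine deterministic threshold-crossing or timer
    components with exponentially distributed stochastic waits.  The
    package generates single-cell life histories along a lineage,
    converts them into simulated asynchronous flow-cytometry samples
    (DNA content versus total cyclin with instrument noise), and runs
    event-driven population simulations of contact-inhibited growth
    with density-dependent G1a exit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
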