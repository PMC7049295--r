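Package: qsswarm
Title: Agent-Based Simulation of Quorum Sensing in Biohybrid Microrobot Swarms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coupled stochastic simulation of bacteria-based biohybrid
    microrobot swarms. Motility of NanoBEADS and BacteriaBots is driven by
    in-sequence replay of tracked (speed, turn-rate) data or by statistically
    matched synthetic trajectory libraries; free-swimming bacteria follow a
    run-and-tumble chemotaxis model. Agents carry an intracellular
    quorum-sensing gene circuit (AHL synthesis with positive feedback, GFP
    reporter maturation and degradation) coupled to an extracellular
    reaction-diffusion signal field, enabling prediction of emergent
    activation times, circuit-sensitivity sweeps, and decentralized-control
    scenarios over spatially separated subpopulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
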