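Package: insoleGait
Title: Simulation and Gait Phase Detection for a Pressure-Sensing Insole Matrix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling an instrumented-shoe plantar pressure system
    and detecting gait events from its output. Includes a resistor-network
    simulation of a row/column force-sensitive film matrix with both naive
    (crosstalk-afflicted) and zero-potential readout, a generative model of
    piezoresistive sensing units including the delayed post-unloading
    response, a synthetic gait trial generator with ground-truth events and a
    synchronized vertical ground reaction force trace, a peak-heuristic
    detector for heel contact, forefoot contact, heel off and toe off with
    the derived stance sub-phase durations, and an evaluation framework
    computing timing errors against force-plate style reference events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
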