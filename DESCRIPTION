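Package: poreadmit
Title: Equivalent-Circuit Analysis of Transient Fusion-Pore Openings from
    Lock-In Admittance Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing unitary exocytic events recorded by
    cell-attached membrane-capacitance (lock-in admittance) measurements.
    Implements the patch equivalent-circuit forward model for the admittance
    change produced by a fused vesicle with a finite fusion-pore conductance,
    the inversion that recovers vesicle capacitance (Cv) and fusion-pore
    conductance (Gp) from the real and imaginary admittance steps, phase
    calibration from periodic capacitance pulses, step detection and on/off
    pairing, and classification of transient (kiss-and-run) events into the
    three canonical cases (zero, incremental, decremental Re projection).
    Includes a synthetic lock-in trace generator with ground truth so every
    stage of the pipeline can be validated without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
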