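Package: ribeam
Title: Radioactive Ion Beams: Microdosimetric RBE, SOBP Design and
    Annihilation-Map Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating positron-emitting radioactive ion beams
    (10C, 11C, 15O) against their stable analogs (12C, 16O) in heavy-ion
    therapy. Implements the modified microdosimetric kinetic model (MKM) for
    RBE10 from lineal-energy spectra, non-negative least-squares construction
    of spread-out Bragg peaks (SOBP) delivering a flat biological dose, the
    stable-to-radioactive beam-spectrum mapping, a seeded parametric generator
    of depth-dose curves, lineal-energy spectra and positron-annihilation
    events standing in for Monte Carlo transport, multi-exponential
    time-activity-curve decomposition with fixed half-lives, spill-gated
    annihilation maps with contrast-to-noise scoring, and bulk incidental-dose
    estimates for radioactive beams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse,
    jsonlite
Config/testthat/edition: 3
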