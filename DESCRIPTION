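Package: ionct
Title: Single-Event Proton and Helium CT: Simulation, Likelihood-Based
    Filtering and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for list-mode (single-event) proton and helium computed
    tomography. Provides the electromagnetic interaction models used in
    particle imaging (Bethe stopping power, CSDA range and water-equivalent
    path length conversion, Fermi-Eyges multiple Coulomb scattering moments
    with Highland's correction, Tschalar thick-absorber energy straggling),
    a condensed-history Monte Carlo simulator with truth-labelled nuclear
    interaction channels, most-likely-path estimation by a phenomenological
    cubic spline through a prior relative stopping power map, the
    pixel-statistics sigma filter and a per-particle likelihood filter that
    rejects nuclear-interaction events by comparing each particle's measured
    exit position, direction and water-equivalent path length against the
    electromagnetic prediction through the prior map, distance-driven-binning
    filtered backprojection with tomographic noise reconstruction, and
    evaluation utilities (confusion counts against Monte Carlo truth, ROC
    curves, region-of-interest noise and stopping-power accuracy tables).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
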