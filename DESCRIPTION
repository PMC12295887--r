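Package: pevkactin
Title: Kinetic Simulation and Quantitative Analysis of PEVK-Modulated
    Actin Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how titin's intrinsically disordered PEVK
    domain modulates actin polymerization. Provides an Oosawa-type
    nucleation-elongation simulator that emulates pyrene-fluorescence
    polymerization assays (including photobleaching and intermittent
    illumination schedules), extraction of initial, half-maximal and peak
    trace metrics, steady-state critical-concentration estimation with
    bootstrap inference, worm-like-chain geometry of disordered protein
    domains in the sarcomeric lattice, and synthesis plus 2D-FFT
    periodicity analysis of AFM-like height images of filament
    paracrystals and radial asters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
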