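Package: poreforce
Title: Membrane Breakthrough Force Analysis and Pore Free-Energy Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the resistance of lipid membranes against pore
    formation from two complementary directions. On the experimental side it
    analyses atomic force microscopy (AFM) indentation curves on
    solid-supported bilayers: baseline correction, contact-point and
    breakthrough-event detection, yield-force statistics, and fitting of a
    continuum nucleation model that recovers the line tension and spreading
    pressure of the membrane from the yield-force distribution under dynamic
    loading. On the simulation side it reconstructs potentials of mean force
    for pore formation along a transmembrane chain coordinate from
    umbrella-sampling series via the weighted histogram analysis method
    (WHAM) with Bayesian bootstrap errors, and translates simulation-box pore
    free energies to experimentally sized membranes through an area-scaling
    relation. Synthetic-data generators for force curves, yield-force
    populations, umbrella series and toy membrane snapshots provide fully
    reproducible inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    signal,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
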