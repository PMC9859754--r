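Package: cometsim
Title: Stochastic Simulation and Image Analysis of Motor-Driven Cargo
    Accumulation at Growing Microtubule Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact (Gillespie) stochastic simulation of a growing
    one-dimensional lattice model of plus-end directed molecular motors
    with Langmuir kinetics, multi-layer cargo binding, a hydrolysing
    GTP cap that slows motors near the tip, coherently moving cargo
    trains and dwell-time stabilization of cargo clusters. Includes
    tip-aligned density profiles, motor-concentration sweeps and a
    non-linearity index for end accumulation, together with the
    microscopy-side analysis pipeline (rolling-ball background
    subtraction, comet intensity-profile binning/alignment/averaging,
    condition ratios, condensate segmentation and client recruitment,
    trace velocity statistics) and synthetic-data generators (kymograph
    rendering, parametric comet profiles, two-channel condensate
    images, motile traces) with full ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
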