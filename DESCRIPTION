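Package: flowbrush
Title: Confined Two-Aperture Perfusion Modelling and Fluorescence Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced-order modelling of the confined laminar flow envelope formed
    between an injecting and an aspirating micropipette aperture (point
    source-sink superposition with substrate image system), dimensionless
    transport analysis (Stokes-Einstein, Peclet, Damkohler, Reynolds),
    Brownian-advective tracer simulation, a synthetic fluorescence-microscopy
    data generator (punctual labeling, FRAP, extended labeling, two-channel
    colocalization, coalescing cluster time lapses), diffusion-coefficient
    estimation from labeling decay and bleach recovery, and image
    quantification: spot detection and linking, velocimetry maps, kymographs,
    Mander's colocalization coefficients, cluster time courses and MSD analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
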