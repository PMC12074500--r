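Package: bfdhm
Title: Single-Capture Bright-Field and Off-Axis Holographic Microscopy
    Demultiplexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward simulation and numerical demultiplexing of grayscale
    dynamic-range multiplexed micrographs that superimpose an incoherent
    bright-field image with an off-axis digital hologram in a single 8-bit
    camera exposure. Provides an optics/geometry model, a phantom-based
    image synthesizer with controllable coherent and incoherent
    illumination powers and noise, Fourier-filtering recovery of
    quantitative phase images (carrier location, cross-band demodulation,
    reliability-sorting phase unwrapping, polynomial aberration
    compensation, background subtraction, phase-to-thickness conversion),
    weighted-subtraction recovery of noise-reduced bright-field images
    with background-noise-minimizing weight optimization, and
    illumination-power characterization sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
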