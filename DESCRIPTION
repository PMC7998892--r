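Package: naagif
Title: Optical Simulation and Release-Kinetics Analysis for Nanoporous
    Anodic Alumina Gradient-Index Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward optical modelling and analysis tools for drug loading
    and release monitoring with nanoporous anodic alumina gradient-index
    filters (NAA-GIFs). Builds discretized sinusoidal rugate stacks from
    anodization design parameters, mixes aluminium oxide, release medium
    and an absorbing cargo molecule with the Bruggeman effective-medium
    rule (Lorentz-oscillator cargo dielectric), computes reflectance by the
    transfer-matrix method, extracts the signal/reference stopband height
    ratio used as the loading observable, and fits the anchored exponential
    release model to flow-cell band-ratio time series. Includes a synthetic
    data generator for drop/dry loading series and flow-cell release
    experiments, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
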