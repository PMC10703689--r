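Package: SBSmicro
Title: Analysis of Pulsed Stimulated Brillouin Scattering Microscopy Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for stimulated Brillouin scattering (SBS) microscopy:
    closed-form stimulated Brillouin gain physics (Lorentzian resonances,
    pulse-scheme duty-cycle enhancement, complex longitudinal modulus),
    synthetic shot-noise-limited spectrum and raster-scan generation,
    single- and multi-Lorentzian spectral fitting with derivative-offset
    single/multi-peak classification, serpentine scan reconstruction into
    per-pixel Brillouin shift, linewidth, gain and SNR maps, and instrument
    metrology (spectral and spatial resolution, precision-versus-integration-
    time scaling, scan-range accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    signal,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, Spectroscopy, Elastography
RoxygenNote: 7.3.3
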