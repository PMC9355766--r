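Package: dentineMP
Title: Multiphoton Microscopy Analysis of Human Dentine Aging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies age-related change in human dentine from paired
    two-photon excitation fluorescence (TPEF) and second harmonic
    generation (SHG) microscopy images. Implements the INAG intensity
    contrast index, peritubular width morphometry by Hough-transform
    orientation detection and perpendicular cross-section valley spacing,
    structure-tensor structural dispersion, and inversion of
    three-polarization SHG stacks into signed hyperpolarizability-ratio
    (rho) maps, together with per-specimen aggregation and age
    regressions. A synthetic image generator produces TPEF/SHG pairs,
    polarimetric stacks and whole cohorts with known ground truth so that
    every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Regression
RoxygenNote: 7.3.3
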