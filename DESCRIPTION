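Package: smfretr
Title: Photon-Stream Analysis for Single-Molecule FRET Lifetimes and
    Fluorescence Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for time-tagged photon streams from
    immobilized single-molecule FRET experiments and diffusing-particle
    fluorescence correlation spectroscopy (FCS). Provides change-point
    segmentation of binned intensity traces under a Poisson likelihood,
    photobleaching-step classification and single-pair trace selection,
    bunch-wise maximum-likelihood donor lifetime fitting with circular
    instrument-response-function convolution, conversion of lifetimes to
    FRET efficiencies and donor-acceptor distances, multi-tau
    autocorrelation with one-species 3D diffusion model fitting,
    Stokes-Einstein hydrodynamic radii, and Debye-Hueckel salt-screening
    fits. A synthetic photon-stream and Brownian-dynamics generator with
    full ground-truth bookkeeping makes every stage testable without
    experimental data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
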