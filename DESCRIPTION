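Package: nanofp
Title: Single-Molecule Nanopore Fingerprinting of Protein-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule protein-drug interaction
    sensing with large funnel-shaped biological nanopores. Provides a
    physics-based synthetic trace generator (1D Brownian dynamics on a
    double-well free-energy landscape, continuous-time Markov level
    switching, white/flicker noise, 8-pole Bessel filtering), event
    detection and dwell kinetics, multi-level blockade segmentation and
    open probabilities, periodogram-based current-noise (I_N) statistics,
    two-dimensional blockade-versus-noise drug fingerprinting with Gaussian
    mixture population models, equilibrium binding (K_D) fits from titration
    event counts, competition time-course analysis, and closed-form pore
    biophysics (funnel conductance, Goldman-Hodgkin-Katz ion selectivity,
    ion flux to current conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    minpack.lm,
    jsonlite,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'bessel.R'
    'detect.R'
    'fingerprint.R'
    'generator.R'
    'io.R'
    'landscape.R'
    'levels.R'
    'nanofp-package.R'
    'noise.R'
    'pipeline.R'
    'pore.R'
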