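Package: radialtherm
Title: Continuous Golden-Angle Radial MR Thermometry with Catheter Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring radiofrequency ablations with ungated
    golden-angle radial gradient-echo MRI. Implements micro-coil catheter
    tracking from pairs of consecutive radial projections, per-spoke rigid 2D
    motion correction in k-space, motion-state multibaseline library building,
    and direct proton-resonance-frequency temperature estimation from highly
    undersampled radial k-space via a hybrid multibaseline/referenceless model
    fitted without an intermediate image reconstruction. A synthetic
    acquisition simulator with known motion, heating and background phase makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    signal,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'raw_io.R'
    'simulate.R'
    'recon.R'
    'library.R'
    'thermometry.R'
    'preprocess.R'
    'tracking.R'
    'pipeline.R'
    'experiments.R'
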