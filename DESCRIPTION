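Package: rowdplan
Title: Hypoxia-Adapted RBE- and OER-Weighted Dose Optimization for Proton
    Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for planning intensity-modulated proton therapy in
    hypoxic tumors. Implements an oxygen enhancement ratio (OER) model
    driven by voxel partial oxygen pressure (pO2) and dose-averaged linear
    energy transfer (LET), hypoxia-scaled linear-quadratic radiosensitivity
    parameters for constant and variable RBE models, photon-equivalent
    RBE-and-OER-weighted dose (ROWD) computation, an analytical pencil-beam
    dose and LET engine, and an iterative dose-difference spot-weight
    optimizer that delivers homogeneous ROWD to a target while escalating
    physical dose and LET in hypoxic subvolumes. Includes a water-phantom
    and synthetic pO2-field generator, DVH/LET-volume-histogram metrics,
    and NIfTI/CSV/JSON readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    oro.nifti,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'radiobio.R'
    'rowd.R'
    'beam.R'
    'optimizer.R'
    'phantom.R'
    'metrics.R'
    'io.R'
    'cli.R'
    'rowdplan-package.R'
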