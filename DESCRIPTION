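Package: megadyn
Title: Temporal Dynamics of Edited-MRS Neurometabolites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of the temporal dynamics of GABA+ and Glx measured with
    MEGA-PRESS edited magnetic resonance spectroscopy. Provides a synthetic
    MEGA-PRESS cohort generator with known ground truth, per-transient
    creatine-referenced frequency and phase correction with outlier rejection,
    Lorentzian/Gaussian peak-model quantification of tCr, tNAA, GABA+ and Glx,
    a low-resolution sliding-window group analysis with cluster-based
    permutation inference, and a high-resolution across-subject binning
    analysis with lag-constrained cross-correlation and cluster correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'preprocess.R'
    'lineshapes.R'
    'quantify.R'
    'dynamics-low.R'
    'dynamics-high.R'
    'megadyn-package.R'
    'truth.R'
    'profiles.R'
    'synthetic.R'
    'pipeline.R'
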