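Package: steadynet
Title: Inference of Microbial Ecological Networks from Steady-State Samples
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-free inference of microbial interaction types (the
    sign-pattern of the community Jacobian) from cross-sectional steady-state
    absolute-abundance samples, a consistency test for generalized
    Lotka-Volterra (GLV) dynamics, and quantitative inference of GLV
    interaction strengths and intrinsic growth rates with Lasso
    regularization and knockoff-filter control of the false-discovery rate.
    Includes population-dynamics simulators (GLV, Holling type II,
    DeAngelis-Beddington, Crowley-Martin) for generating validation data on
    random taxon-presence supports with multiplicative measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, NetworkInference, Regression, Software
RoxygenNote: 7.3.3
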