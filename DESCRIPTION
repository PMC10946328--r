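Package: cascadefit
Title: Bayesian Modeling of Gene Expression Cascades Along Pseudotime Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits parametric response functions (uniform, Gaussian, sigmoidal,
    double sigmoidal) to pseudotime-ordered single-cell UMI counts under a
    negative-binomial likelihood with a globally estimated dispersion, using an
    affine-invariant ensemble MCMC sampler. Models are compared with a
    subsample-based Bayesian information criterion, and signed inflection
    points extracted from the posterior draws are used to order genes along
    transcriptional cascades, quantify overlap in switch timing, and infer
    directed regulatory interactions between genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
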