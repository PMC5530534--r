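Package: funbandr
Title: Bayesian Functional Regression for Multi-Environment Hyperspectral
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for predicting a primary agronomic trait (grain yield)
    from plot-level hyperspectral reflectance measured across multiple
    environments, combined with genomic or pedigree relationship
    information.  Implements a two-stage analysis of alpha-lattice field
    trials (per-environment REML and weighted BLUEs), scalar-on-function
    regression of yield on reflectance curves through B-spline or Fourier
    bases with roughness-penalty priors, a catalogue of fourteen
    hierarchical models with genotype-by-environment and
    band-by-environment interactions, a Gibbs sampler for the resulting
    Bayesian linear models, cross-validation schemes used in
    multi-environment plant breeding trials, and a synthetic-trial
    generator with exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    Rcpp,
    splines,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
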