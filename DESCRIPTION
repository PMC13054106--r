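Package: btlam
Title: Bayesian Threshold-Linear Animal Models for Growth and Fertility Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait Bayesian animal models combining continuous growth
    traits with an ordinal fertility trait on the liability scale. Provides
    pedigree algebra (numerator relationship matrix, inbreeding, Henderson's
    sparse inverse), the data-preparation rules used in beef-cattle genetic
    evaluation (outlier trimming, contemporary groups, sire progeny filters),
    a Gibbs sampler with liability augmentation for a two-continuous plus
    one-ordinal trait model, posterior summaries with Monte Carlo error,
    effective sample size and Geweke diagnostics, breeding-value ranking
    analyses, and a pedigree/phenotype simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
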