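Package: robustsire
Title: Robust Bayesian Sire Models with Heavy-Tailed Residuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian multi-trait linear mixed models for genetic evaluation
    in which residuals follow a multivariate Student's-t distribution with
    unknown degrees of freedom, represented as a scale mixture of normals.
    Provides a Gibbs sampler with a random-walk Metropolis-Hastings update
    for the degrees of freedom, sire and sire-maternal-grandsire models with
    pedigree relationship matrices, transformation of sire-MGS components to
    direct/maternal animal-model parameters (heritabilities and genetic
    correlations), predictive log-likelihood (CPO harmonic mean) model
    comparison, Geyer initial-positive-sequence effective sample sizes,
    mixing-scale outlier diagnostics, and a simulator reproducing the
    structure of heavy-tailed bivariate sire data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
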