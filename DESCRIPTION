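Package: mutcov
Title: Mutational (Co)variance Matrices from Movement-State Transition Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and comparison of mutational (M) and standing genetic
    (G) variance-covariance matrices for nematode locomotion behavior traits.
    Provides continuous-time Markov chain estimation of transition rates
    between forward, still and backward movement states from discretely
    observed state sequences; univariate linear mixed models for genetic
    background effects and mutational bias; a Gibbs sampler for multivariate
    mixed models with inverse-Wishart priors yielding posterior distributions
    of line, block and residual covariance matrices; randomized-null matrix
    construction by label permutation; matrix comparison statistics
    (eigendecomposition, folded angles between leading eigenvectors, variance
    projections and their null expectations); and genetic covariance tensor
    analysis across sets of matrices. A synthetic-data module simulates all
    inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    MASS,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
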