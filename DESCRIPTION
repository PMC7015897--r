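Package: polyGP
Title: Bayesian and Convolutional Neural Network Genomic Prediction for Polyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and genomic prediction toolkit for polyploid species
    with allele-dosage genotypes. Simulates dosage genotypes (any even ploidy)
    and complex traits under additive, multiplicative-epistatic, and mixed
    architectures with heritability calibration; builds additive, dominance
    (diploid and autotetraploid), epistatic and Gaussian genomic relationship
    kernels plus dosage-class dummy designs; fits Bayesian whole-genome
    regressions (Bayesian ridge, Bayesian lasso, dosage-class ridge, RKHS and
    multi-kernel variance decomposition) by Gibbs sampling; trains small
    one-dimensional convolutional networks on SNP dosages with random
    hyperparameter search and random-forest hyperparameter importance; and
    drives replicated simulation studies comparing the methods by predictive
    ability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
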