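Package: dgindex
Title: Iterative Desired-Gain Selection Indices for Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes desired-gain selection indices from genetic and
    phenotypic covariance matrices and iteratively optimises the sampled
    desired-gain vector so that the realised multi-trait selection response
    of a truncation-selected subset matches a breeder-specified target.
    Includes index algebra via stable linear solves, empirical standardized
    selection response, a stochastic accept/reject optimiser with replicate
    consistency checks, a multivariate-normal simulator of genomic estimated
    breeding values with specified heritabilities, genetic correlations and
    prediction accuracies, delimited-text readers and writers, and an
    end-to-end pipeline with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
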