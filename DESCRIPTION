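Package: thinsim
Title: Data-Based RNA-Seq Simulation by Binomial Thinning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Adds a user-specified signal to a real or synthetic RNA-seq
    count matrix by binomial thinning. Signal is specified on the log2
    scale through arbitrary design and coefficient matrices, so that all
    unwanted variation present in the source data is preserved in the
    simulated data. Supports two-group differential-expression benchmarks,
    library-size thinning, correlation targeting between injected
    covariates and latent factors (via surrogate estimation, a
    conditional-normal draw, and optimal row matching), proportion of
    variance explained summaries, and a synthetic count generator for
    Poisson, negative binomial, and zero-inflated negative binomial base
    data. Includes a command-line interface with reproducible run
    manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
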