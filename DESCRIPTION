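Package: recombpast
Title: Reconstructing Past Changes in Locus-Specific Recombination Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coalescent simulation and inference tools for reconstructing the
    recombination history of a genetic locus. Implements a Kingman coalescent
    simulator with recombination in which the recombination rate follows a
    user-specified trajectory through time (constant, linear, exponential or
    logistic), a suite of nine recombination-sensitive summary statistics
    (segregating sites, Rmin, the Myers-Griffiths haplotype bound, haplotype
    counts and diversity, Wall's B and Q, Hudson's C and ZnS), an n-tuple
    subsampling bootstrap that converts a single contemporary sample into
    feature distributions informative about recombination at different time
    depths, and linear/quadratic discriminant classification with jackknife
    cross-validation to assign loci to recombination-history models. Closed
    form coalescent expectations bounding the power of the approach are also
    provided.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
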