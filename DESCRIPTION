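Package: tensorphase
Title: Haplotype Assembly of Diploids and Polyploids by Sparse Tensor
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles haplotypes of diploid and polyploid (biallelic and
    polyallelic) genomes from SNP fragment data by casting phasing as a
    structured, masked low-rank tensor decomposition. Sequencing reads are
    one-hot encoded into a sparse binary tensor and factorized into a
    read-origin indicator matrix and a haplotype tensor by alternating
    exact read reassignment with a projected gradient step on the relaxed
    minimum-error-correction objective, starting from a spectral
    (power-iteration SVD) initialization. Includes MEC and correct phasing
    rate scoring, a paired-end SNP fragment simulator with geometric
    inter-SNP spacing and a uniform substitution error model, and
    evaluators for the incoherence-based theoretical coverage conditions
    and MEC/CPR performance bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
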