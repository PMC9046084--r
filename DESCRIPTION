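Package: bulkdecon
Title: Bayesian Deconvolution of Bulk RNA-seq Using Single-Cell References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian inference of cell type and cell state fractions
    and cell-type-specific gene expression from bulk RNA-seq, using a
    reference of multinomial expression profiles built from labelled
    scRNA-seq data. A Dirichlet-multinomial mixture model is fit per bulk
    sample by Gibbs sampling; the reference is then updated by pooling
    reads across samples (maximum a posteriori estimation under a
    log-normal fold-change prior for nonmalignant cell types, per-sample
    maximum likelihood for the malignant type) and fractions are
    re-estimated. Additional modules learn malignant gene programs by
    expectation-maximization with fixed nonmalignant components, screen
    for genes whose malignant-cell expression tracks the fraction of a
    nonmalignant cell type, score deconvolved expression against
    signature profiles, and simulate pseudo-bulk cohorts with known
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
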