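Package: mixdecon
Title: Simulated Multi-Omic Mixtures and Benchmarking of Reference-Free
    Cell-Type Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate paired bulk transcriptome and DNA-methylation
    profiles of heterogeneous tumor samples as linear mixtures of cell-type
    reference profiles with Dirichlet-distributed proportions, together with a
    set of reference-free deconvolution pipelines (stability-filtered ICA
    feature selection, weighted-ICA proportion estimation, sparse and
    constrained non-negative matrix factorization with simplex and box
    constraints) and a benchmarking harness that scores estimated proportion
    matrices by permutation-matched mean absolute error, builds leaderboards,
    and renders graphical reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    MASS,
    pracma,
    jsonlite,
    ggplot2,
    pheatmap
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
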