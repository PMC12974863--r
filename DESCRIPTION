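Package: ecocline
Title: Forward-Time Simulation and Diagnosis of Bacterial Ecoclines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based, non-Wright-Fisher forward simulation of
    recombining haploid bacterial populations under neutral, stepping-stone,
    rate-heterogeneity and diversifying-selection scenarios, together with
    the diagnostic stack used to characterise clinal population structure:
    binary minor-allele SNP matrices with MAF filtering and windowed LD
    pruning, principal component analysis with per-variant loadings and
    cross-group projection, three half-matching reproducibility tests,
    linkage-disequilibrium decay curves and block clustering, and
    neighbour-joining trees with a quantitative phylogenetic backbone score.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
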