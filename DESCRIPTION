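Package: pairGWAS
Title: Phylogeny-Aware Microbial Genome-Wide Association with Contrasting Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores pan-genome gene presence/absence against many binary or
    automatically binarized continuous phenotypes across bacterial isolates.
    Population structure is handled with a phylogeny-aware contrasting-pairs
    statistic and a label-switching permutation test; continuous phenotypes
    are binarized with two-cluster k-means or a two-component Gaussian
    mixture with a posterior-probability abstention rule. Emits ranked,
    multiple-testing-corrected candidate gene tables, a trait-clustering
    overview, and per-trait data bundles, and ships a simulator for
    tree-evolved pan-genomes with a causal gene driving a Gaussian phenotype.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
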