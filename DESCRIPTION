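Package: mirwave
Title: MicroRNA Annotation Filtering and Expression Dynamics Across the
    Maternal-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-RNA/mRNA developmental transcriptomics built
    around the maternal-zygotic transition. Implements read-stack based
    post-filtering of microRNA precursor candidates (arm read support, loop
    length, 5' end homogeneity, conservation rescue), relative arm-usage
    statistics and developmental/evolutionary arm-switching classification,
    seed-and-extend homology search of precursors across genomes with
    family presence/absence profiling and species clustering,
    median-of-ratios normalization with fuzzy c-means time-course
    clustering and elbow-based model selection, negative-binomial Wald
    tests between adjacent developmental stages summarised as waves of
    zygotic genome activation, and seed-match target prediction with
    nearest-neighbour duplex free energies, hypergeometric enrichment and
    Mann-Whitney burden tests. A synthetic-data module generates every
    input with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    DESeq2,
    phangorn,
    jsonlite
Config/testthat/edition: 3
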