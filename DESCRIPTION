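Package: epinetscan
Title: Genome-Wide Pairwise SNP-SNP Epistasis Scan and Interaction
    Network Analysis for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exhaustive two-locus epistasis analysis of a
    quantitative trait in a family-structured population: marker and
    individual quality control, a Kempthorne-style partition of each
    two-locus interaction into additive-by-additive, additive-by-dominance,
    dominance-by-additive and dominance-by-dominance one-degree-of-freedom
    effects using frequency-orthogonal contrast codings valid under
    Hardy-Weinberg and linkage disequilibrium, F-tests with Bonferroni
    control over all pairs, contribution rates (percent phenotypic
    variation explained), construction of the SNP-SNP interaction network
    with an entropy-motivated subnet importance score, and genomic window
    annotation (fragment union regions, QTL and gene overlap, pathway
    tallies).  Includes a synthetic-cohort generator with planted epistatic
    effects so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    igraph,
    lme4,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
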