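Package: mkpipe
Title: Keystone Taxa and Multi-Omics Integration for Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying keystone gut microbial taxa and
    linking them to host gene expression and continuous phenotypes. Implements
    rare/abundant/conditional abundance-class partitioning of ASV tables
    (RT/AT/MT/CRT/CAT/CRAT), prevalence and total-abundance filtering, TMM
    scaling-factor normalization, alpha diversity, Bray-Curtis ordination
    (PCoA) with one-way PERMANOVA, point-biserial indicator-species analysis
    with a max-statistic permutation null, specificity-occupancy key-species
    calling, Spearman co-occurrence networks with centrality-based keystone
    detection, negative-binomial and permutation differential-feature tests
    with Benjamini-Hochberg correction, Procrustes/PROTEST concordance between
    ordinations, and a typed taxon-gene-trait correlation network. Ships a
    seeded synthetic-data generator (Gaussian-copula log-normal to multinomial
    counts, coupled negative-binomial expression, trait panels) with a planted
    ground-truth record so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
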