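Package: panconcord
Title: Pan-Genome, Biosynthetic Gene Cluster and Metabolome Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative comparison of phylogeny, biosynthetic gene cluster
    (BGC) content and untargeted metabolomes for bacterial strain collections.
    Provides pan-genome core/accessory/singleton partitioning with
    coordinate-based mapping of biosynthetic genes, BGC novelty summaries,
    gene cluster family (GCF) presence matrices and metabolite feature tables,
    Jaccard and Bray-Curtis dissimilarities with UPGMA dendrograms, dendrogram
    concordance statistics (cophenetic Pearson correlation, Baker's Gamma)
    with leaf-permutation null models, Mantel tests, principal coordinate
    analysis and PERMANOVA, and random-forest variance attribution across
    grouping criteria (phylogeny, isolation source, culture medium). A
    seeded synthetic-data generator with known effect sizes makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
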