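Package: strokenet
Title: Integrative Genetic Analysis of Ischemic Stroke Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for case-control studies of ischemic stroke
    that integrates single-locus quality control and association with
    systems-level interaction analyses. Provides Hardy-Weinberg equilibrium
    testing, SNP versus risk-factor association scans, model-based causal
    mediation analysis (average causal mediation effect with quasi-Bayesian
    Monte-Carlo intervals) for genotype -> risk-factor -> outcome pathways,
    multifactor dimensionality reduction (MDR) for SNP-SNP interaction search
    with cross-validation, permutation testing and entropy-based interaction
    graphs, and a shared-miRNA competing-mRNA (ceRNA) network built from a
    hypergeometric overlap test, with centrality ranking and gene-set
    over-representation analysis. Includes seeded synthetic-data generators
    for every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    fgsea,
    knitr
Config/testthat/edition: 3
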