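Package: cohortmapper
Title: Topological Stratification of Clinicopathobiologic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for endotype discovery in mixed
    clinical/immunological cohort matrices. Provides a seeded synthetic
    cohort generator with planted phenotype profiles, subgroup-mean
    imputation and compartment-composite preprocessing, a from-scratch
    Mapper (topological data analysis) implementation with SVD lenses,
    equalized overlapping covers and Kolmogorov-Smirnov cluster
    characterization, discrete Bayesian-network structure learning with
    BIC hill climbing and edge-sign classification, a nonparametric
    group-comparison battery (Kruskal-Wallis with Dunn post hoc,
    Jonckheere-Terpstra, polynomial trend contrasts, Spearman,
    two-sample Kolmogorov-Smirnov), and sputum granulocytic subtype
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
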