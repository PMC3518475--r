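Package: oligomiR
Title: MicroRNA qPCR Profiling of Oligo- and Polymetastatic Progression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking microRNA expression in resected lung
    metastases to the rate of metastatic progression. Stratifies patients into
    high/low/intermediate rate-of-progression phenotypes (HRP/LRP/IRP) and
    oligo- vs polymetastatic progression (OM/PM) from recurrence timelines;
    quality-controls and normalizes TaqMan-array-style Ct matrices (delta-Ct
    against pooled endogenous controls, or quantile normalization); computes
    signed delta-delta-Ct fold changes with unadjusted t-tests; assesses
    congruent co-expression of microRNA families and -3p/-5p strand pairs by a
    label-shuffling permutation statistic; tests phenotype enrichment in
    dendrogram branches (average linkage, 1-Pearson distance, two-sided Fisher
    exact tests, F-distribution proportion intervals); and compares survival
    by Kaplan-Meier and log-rank statistics. Includes a seeded synthetic
    cohort generator emulating the cohort structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    limma,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
biocViews: GeneExpression, qPCR, Clustering, Survival, miRNA
Config/testthat/edition: 3
RoxygenNote: 7.3.3
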