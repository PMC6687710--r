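Package: proteogx
Title: Proteogenomic Analysis of Multiplexed Tumor Proteomics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for quantitative proteogenomics of
    isobarically labeled (TMT) tumor cohorts: target-decoy two-step FDR
    protein-group assembly, pool-referenced cross-plex bridging of reporter
    intensities into a single cohort abundance matrix, consensus-clustering
    subtype discovery with CDF-area model selection, subtype-genotype
    association statistics (rank-sum differential expression, exact tests,
    ordinal Cochran-Mantel-Haenszel), copy-number/transcript/protein
    correlation integration with a dependency-screen vulnerability cascade,
    and survival meta-analysis across omic layers with empirical-Bayes
    heterogeneity and Storey q-value selection. Ships a fully specified
    synthetic cohort generator with known ground truth so the whole
    pipeline is testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    survival,
    metafor,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
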