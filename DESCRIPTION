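Package: prspleio
Title: Cross-Cancer Polygenic Risk Score Pleiotropy Pipeline
Version: 0.1.0
Authors@R:
    person("Maintainer", "prspleio", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building cancer-specific polygenic risk scores (PRS)
    from a literature variant-association catalog and scanning them across
    cancer and non-cancer phenotypes in multiple cohorts. Implements catalog
    curation (deduplication, genome-wide-significance and ancestry filters),
    allele harmonization against a genotype panel with proxy resolution and
    strand-ambiguity handling, priority LD pruning, dosage-based PRS
    construction and standardization, covariate-adjusted logistic and linear
    association scans, inverse-variance fixed-effects meta-analysis with
    Cochran's Q and I-squared, Bonferroni and Benjamini-Hochberg multiplicity
    control, genomic-region enrichment, and sensitivity refits of filtered
    scores. A synthetic-data module generates two-cohort fixtures with
    LD-block genotypes, planted harmonization traps and known effect sizes so
    the full pipeline is testable without access-controlled cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
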