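Package: methcross
Title: Cross-Species DNA Methylation Analysis for Bisulfite Counts and
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for comparing DNA methylation between a murine
    tumour model and human tumour methylome datasets. Reads per-CpG
    bisulfite read counts (Bismark coverage format) and array-style
    beta-value matrices, computes beta- and M-values, filters loci by
    coverage and methylated-read support, calls differentially
    methylated CpGs with empirical-Bayes moderated t-statistics on
    M-values, agglomerates CpGs into candidate regions tested by
    beta-binomial regression, clusters samples on the most variable
    loci, resolves mouse-human orthologs by homology tie-breaking
    rules, and quantifies cross-species enrichment and
    direction-concordance of differential methylation. A synthetic-data
    generator with known ground truth makes every stage testable
    without access to controlled raw data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
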