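Package: hdmomics
Title: Multi-Omics Analysis of Allergen-Exposed Mouse Lung Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a multi-omics analysis
    pipeline for a two-group (house dust mite allergen vs vehicle), two-tissue
    (normal lung vs tumor) mouse study design: ensemble somatic-variant
    consensus filtering and post-calling filters, SBS96/DBS78/ID83 mutational
    spectrum classification and cosine comparison, negative-binomial
    differential expression with median-of-ratios and TMM normalization,
    curated gene-module scoring, preranked gene-set enrichment, marker-based
    immune deconvolution scores, site- and region-level differential DNA
    methylation, and promoter methylation-expression integration with an
    inverse-correlation screen for epigenetically controlled genes. A
    self-contained synthetic-data generator with planted ground truth replaces
    the deposited raw sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
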