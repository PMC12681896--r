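Package: clonalpair
Title: Two-Tier Clonality Classification of Tumor Pairs from Mutations and
    Genome-Wide Copy Number Aberrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies the clonal relationship of tumor pairs (intrapulmonary
    metastasis versus separate primary cancers) with a two-tier workflow: an
    adapted IASLC decision tree on panel somatic mutations, backed by a
    genome-wide copy-number classifier that combines the Pearson correlation
    of binned log2 read-count ratios with an arm-level log-likelihood ratio
    weighted by reference-cohort aberration frequencies. Includes binned
    read-count preprocessing (normalization, circular-binary-segmentation
    style segmentation, arm-state calling), readers and writers for bin
    tables, SEG segments, minimal VCF and reference-frequency tables, and a
    seeded synthetic tumor-pair generator emulating shallow whole-genome
    sequencing of lung cancer cohorts so the whole pipeline is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
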