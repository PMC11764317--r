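Package: skindel
Title: Somatic Small Deletions in Non-Melanoma Skin Cancer: Filtering,
    Homopolymer Context and Gene-Set Interaction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic small deletions (DELs) called in
    matched tumour/blood targeted sequencing of non-melanoma skin cancer.
    Provides germline subtraction and quality filtering of variant calls,
    partitioning of DELs into tumour-associated, shared and healthy-skin
    classes by unique genomic coordinate and by gene, homopolymer /
    short-tandem-repeat context annotation against a reference sequence, a
    gene-set ANOVA with tissue-by-deletion and tissue-by-deletion-by-arsenic
    interaction terms yielding stratum fold changes with confidence intervals
    and Bonferroni-adjusted interaction tests, exact two-by-two co-occurrence
    testing of patient-level mutation statuses, and a synthetic-cohort
    generator with recorded ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    edgeR,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
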