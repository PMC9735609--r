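Package: imprintr
Title: Allele-Specific Imprinting Analysis for Triparental Maize Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies maternally and paternally expressed genes (MEGs and
    PEGs) from allele-specific read counts in reciprocal maize crosses,
    including triparental designs in which an F1 hybrid is crossed with a
    third inbred line. Provides informative-SNP selection, per-gene allele
    count aggregation, chi-square dosage tests against the 1:1 (embryo) and
    2:1 (triploid endosperm) nulls, reciprocal-cross imprinting calls,
    cross-comparison conservation set algebra, 1-Mb imprinted-gene cluster
    detection, promoter cis-regulatory element scanning, expression subgroup
    clustering, and a fully seeded synthetic-data generator with known truth
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
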