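Package: mpralleles
Title: Enhancer Variant and Allelic Activity Analysis for Massively
    Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for massively parallel
    reporter assay (MPRA) screens of disease-associated regulatory
    variants. Designs allele-specific oligos from a variant table and a
    reference genome, processes barcode counts into oligo-level count
    matrices, identifies enhancer variants (enVars) with a
    negative-binomial activity test and allelic enVars with a barcode-level
    t-test, performs resampling-based functional-genomics enrichment
    against peak sets, scores allele-specific ChIP-seq read imbalance with
    replicate-consistency filters, classifies variant overlapping versus
    variant adjacent transcription factors with relative PWM scores, and
    assigns tiered target-gene annotations. A seeded synthetic-data module
    generates ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
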