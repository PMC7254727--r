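Package: rnamosaic
Title: Multi-Tissue Multi-Individual Mosaic Mutation Detection from RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and developmental timing of mosaic mutations from
    multi-tissue, multi-individual RNA-seq pileup count data. Implements a
    substitution-class-specific beta-binomial sequencing-error model with
    per-site upper-tail tests and FDR control, multi-sample re-genotyping of
    candidate sites into a variant x tissue x individual genotype array with
    germline subtraction and cohort-level artifact filters, a random-forest
    call filter with max-F1 threshold selection, mapping of surviving calls
    onto an embryogenesis lineage tree to classify early-, mid- and
    late-embryonic mosaic mutations, per-nucleotide mutation-rate estimation
    on constitutively expressed gene sets with exome extrapolation and
    precision/sensitivity correction, confounder-corrected tissue-specific
    somatic rates with age-association tests, and refitting of
    96-trinucleotide-context mutation catalogs against reference mutational
    signatures. A fully synthetic cohort generator (lineage-placed mutations,
    beta-binomial read noise, expression dropout) makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    randomForest,
    ape,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    rtracklayer,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
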