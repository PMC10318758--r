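Package: fuseSV
Title: Resolve Gene Fusions by Matching RNA-Seq Predictions to WGS Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates RNA-seq gene-fusion predictions from two callers with
    paired tumor-normal structural variant (SV) calls from three whole-genome
    sequencing callers. For every predicted chimeric transcript, genomic
    matching intervals are derived from the intron-exon structure of a
    canonical transcript, SV breakends falling in these intervals link the 5'
    and 3' partner genes, a multi-caller consensus is built by reciprocal
    overlap, and fusions are classified as tumor-specific, germline or low
    allele fraction from tumor/normal read support. Resolved fusions are
    annotated against chimera databases, population SVs, repeat tracks and
    cancer-gene lists, and interpreted with copy-number status and expression
    z-scores. A seeded synthetic-cohort generator emits all input dialects
    with a machine-readable truth manifest for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
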