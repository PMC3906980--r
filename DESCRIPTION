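Package: nitroseq
Title: Integrated mRNA and Small RNA Sequencing Analysis of the Root
    Nitrate Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the joint analysis of poly-A+ and
    small-RNA Illumina libraries from nitrate- versus control-treated
    plant roots.  Covers quality/adaptor/size filtering of raw reads,
    perfect-match genome mapping with full multi-locus reporting,
    locus-weighted classification of reads by genomic origin,
    rarefaction (saturation) analysis, a negative-binomial exact test
    for two-condition differential expression with median-of-ratios
    normalization, average-gene-coverage (AGC) stratified concordance
    with microarray data, discovery of novel transcribed regions
    including natural antisense transcripts (NATs), and genomic-context
    annotation of miRNA loci.  A synthetic-data generator with a full
    ground-truth table allows every stage to be exercised and validated
    end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
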