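Package: ernanet
Title: Enhancer RNA Identification and Regulatory Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies enhancer RNAs (eRNAs) and superenhancer lncRNAs from
    interval overlap of lncRNA annotations with enhancer and superenhancer
    catalogues, performs quantile normalisation and paired tumour/normal
    differential expression with fold-change filtering, assigns candidate
    target genes within a genomic window, tests gene-set over-representation,
    and builds an eRNA-(enhancer)-TF-target coordination network from shared
    transcription-factor motifs, chromatin-interaction anchors and CTCF peak
    occupancy. Includes a seeded synthetic-study generator with planted ground
    truth so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    limma,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
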