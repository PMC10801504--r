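Package: dogscan
Title: Detection of Downstream-of-Gene Readthrough Transcripts from RNA-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects downstream-of-gene (DoG) readthrough transcripts from
    RNA-seq coverage by extending fixed-width FPKM windows past annotated 3'
    ends, validates the calls against RNA polymerase II ChIP-seq promoter
    peaks, tests DoG regions and their parent gene bodies for differential
    expression between two conditions with a moderated negative-binomial Wald
    test, and compares DoG sets across conditions and cell lines by gene
    identifier. Includes a synthetic-data generator that plants readthrough
    extensions, interfering downstream genes and promoter peaks with known
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
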