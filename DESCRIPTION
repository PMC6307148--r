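Package: SpliceJudge
Title: Convolutional Classification and Relevance Decomposition of Splice Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies candidate RNA splice junctions from their flanking
    genomic sequence with a small convolutional neural network over paired
    donor/acceptor windows, explains each prediction per nucleotide by deep
    Taylor decomposition (z+ and bounded-box relevance rules), and pre-filters
    junction lists for alignment artifacts caused by repetitive sequence using
    anchor edit distances. Includes a synthetic benchmark generator that
    plants position-weight-matrix donor/acceptor motifs in random genomes,
    GT..AG-anchored decoys and repeat-artifact junctions with known ground
    truth, plus the evaluation metrics customary for splice site
    classification (sensitivity, specificity, Q9, auROC, auPRC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
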