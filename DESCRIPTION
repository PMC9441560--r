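Package: circPepMS
Title: Translatable circRNA Prediction from Mass Spectrometry Peptide
    Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies translatable circular RNAs (circRNAs) from peptide
    sequences reported by tandem mass spectrometry (MS/MS) search engines.
    Builds six-frame reference peptide databases around back-splice
    junctions (BSJs), enumerates circular open reading frames (cORFs) by
    rolling translation over repeated circle copies, detects and merges
    junction-spanning peptide evidence, scores coding potential with a
    naive Bayes classifier, labels internal ribosome entry site (IRES)
    status, classifies translatable circRNAs into six structural classes,
    and self-evaluates with a reverse-complement target-decoy false
    discovery rate. A seeded synthetic-data generator provides circRNAs
    with planted cORFs and junction-spanning peptides for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    e1071,
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
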