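Package: orgatlas
Title: Organellar Proteome Inference and Genome-Structure Statistics for
    Anaerobic Protists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based inference of organellar proteomes in amoebozoan
    protists that carry mitochondrion-related organelles (MROs) and anaerobic
    peroxisomes. Implements peroxisomal matrix-protein calling from PTS1/PTS2
    targeting-signal grammars with a transmembrane filter, mitochondrial
    candidate calling from a multi-predictor N-terminal targeting-sequence
    consensus fused with homology and heterologous-localization evidence,
    strand-aware intron extraction with splice-boundary classification, and
    cross-species organelle-proteome overlap counting. Ships a synthetic-data
    generator that plants targeting signals, predictor evidence and gene
    models with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
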