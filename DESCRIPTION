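Package: dynabind
Title: Differential Cistrome and Nuclear Interactome Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing treatment-induced rewiring of a
    transcription factor's chromatin binding and nuclear protein
    interactions. Classifies ChIP-seq peak sets into lost, retained and
    gained sites between two conditions; annotates peaks against
    stage-specific androgen-receptor binding-site classes; ranks a query
    cistrome against a reference cistrome library with a binned
    Fisher/odds-ratio combo score; processes RIME (rapid
    immunoprecipitation and mass spectrometry of endogenous proteins)
    unique-peptide tables with control-IP subtraction, differential
    interaction classification, profile correlation and Venn-based
    co-factor nomination; ranks ORF-screen differential viability Z-scores
    and RNAi dependency screens; and associates an index gene with
    transcriptome signatures by Spearman correlation with
    Benjamini-Hochberg correction. Ships a synthetic-data generator that
    plants ground truth for every stage so the full pipeline is testable
    without external downloads.
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
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
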