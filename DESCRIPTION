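Package: knobminer
Title: Mining Bovine Ultralong CDRH3 Repertoires for Knob Domain Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a computational
    pipeline for discovering disulphide-rich knob domain peptides from
    bovine antibody ultralong CDRH3 repertoires. Includes a ground-truthed
    synthetic amplicon read generator, barcode demultiplexing and
    motif-anchored CDRH3 extraction from three-frame translations,
    length- and duplication-based ultralong classification with cysteine
    profiling, percent-identity single-linkage clonotyping, knob/stalk
    boundary annotation, design of TEV-cleavable fusion constructs with
    in silico digestion, disulphide-corrected peptide mass and isotope
    envelope prediction, and binding analytics (1:1 Langmuir single-cycle
    kinetics simulation and fitting, four-parameter logistic dose-response
    fitting, and Cheng-Prusoff conversion of IC50 to Ki).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
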