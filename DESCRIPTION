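Package: eranet
Title: Hierarchical Estrogen-Receptor Regulatory Network Inference from
    ChIP Peaks, Motif Scanning and Expression Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed hub-TF to target-TF regulatory networks
    around a ChIP-profiled transcription factor (typically the estrogen
    receptor alpha). Peaks are standardized to a fixed width, localized
    relative to annotated genes with a configurable region taxonomy,
    and assigned to genes with asymmetric upstream/downstream windows
    (100 kb for the factor of interest, 10 kb for Pol-II). Genes bound
    by both antibodies and differentially expressed are scanned with
    hub-TF position weight matrices using log-odds PWM scores and a
    sliding core-region score; each candidate edge is validated by a
    composition-preserving sequence-shuffling permutation test. A
    synthetic-data generator with planted ground truth makes every
    stage testable without external downloads. Networks export to SIF,
    GraphML and tabular forms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
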