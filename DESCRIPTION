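Package: gmoscreen
Title: In Silico PCR Simulation and Screening Matrices for GMO Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates qPCR-based detection of genetically modified organism
    (GMO) events directly from DNA sequence: approximate primer binding-site
    search under bounded mismatch and gap budgets, amplicon enumeration over
    all three primer pairings, TaqMan probe classification, and conversion of
    the pooled hits into 0/1/2 detection scores.  Scores are assembled into
    event-by-method screening matrices and can be inverted: an observed
    pattern of positive and negative screening results is decomposed into the
    minimal single events or mixes of up to three events that explain it.  A
    deterministic synthetic-panel generator with planted binding sites stands
    in for confidential reference sequence collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    utils,
    stats,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
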