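Package: cernet
Title: Competing Endogenous RNA Network Inference from Expression and
    miRNA Target Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from two-group expression matrices, literature-derived miRNA
    evidence, and scored miRNA target predictions. Implements the full
    inference chain: fold-change/t-test differential screening, multi-study
    miRNA catalogue reconciliation (conflict dropping, precursor expansion,
    target-database filtering), score- and correlation-based interaction
    filtering, shared-miRNA triplet assembly, centrality-based hub and key
    lncRNA selection, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, ceRNA-pathway layering, and transcription
    factor target networks from binding-site counts. Ships a seeded synthetic
    data generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
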