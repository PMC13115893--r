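Package: oamethyl
Title: Integrative DNA-Methylation Analysis for Osteoarthritis Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative framework for discovering osteoarthritis-associated
    genes from Illumina 450K DNA-methylation beta values. Implements dual-strategy
    CpG screening (differential-methylation T-pool and effector-gene TSS-window
    G-pool), consensus feature selection by SVM-RFE and random-forest importance
    with cross-validated subset sizing, a dual-branch diagnostic classifier that
    fuses a Transformer encoder and a 1-D convolutional network through a learned
    dynamic gating vector, gradient-saliency biomarker panel selection, and
    downstream gene-level analysis (CpG-to-gene mapping, hypergeometric
    over-representation with FDR control, and composite degree/betweenness hub
    scoring of interaction networks). A synthetic 450K-like cohort generator with
    known planted structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    e1071,
    randomForest,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
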