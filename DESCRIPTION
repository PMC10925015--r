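Package: cdrnet
Title: Cancer Drug Response Prediction with Edge-Aware Graph and Sequence Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the half-maximal inhibitory concentration (ln IC50) of
    anticancer compounds against cancer cell lines by fusing three learned
    representations: a graph convolutional encoder over the molecular graph
    that co-updates atom and chemical-bond embeddings, a transformer encoder
    over frequency-merged SMILES substructure tokens, and four attention-fused
    omics subnetworks (expression, methylation, mutation, copy number).
    Includes SMILES-enumeration data augmentation restricted to the training
    split, seeded synthetic data generators for offline end-to-end testing,
    gradient-sum gene attribution for trained models, and utilities for
    imputing unmeasured drug-cell-line response pairs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    limma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
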