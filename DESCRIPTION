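Package: actin
Title: Attention-Based Convolution Transpositional Interfusion Networks
    for Chemical Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-cell-line prediction of drug-induced gene expression
    changes from molecular graphs and protein-protein-interaction-derived
    gene embeddings. Implements the ACTIN architecture: a GATv2 drug
    encoder with TopK pooling and multiscale readout, a transformer-style
    transpositional interfusion stack over the (gene, drug) token pair,
    and a bounded interaction-score head trained per cell line with
    smooth-L1 loss against step-function-mapped log fold changes. Includes
    a synthetic-data generator with planted chemical-element effects,
    node2vec gene embeddings, evaluation metrics (ROC/PR-AUC, per-instance
    Pearson, confusion matrices, weighted aggregation), element-embedding
    disparity and attention-based element-importance analyses, and
    signature-reversal drug screening.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ChemmineR,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
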