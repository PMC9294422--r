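Package: rbpscreen
Title: Transfer Learning for RNA-Binding Protein Prediction and Proteome Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sequence-classification toolkit for predicting RNA-binding
    proteins (RBPs) from protein sequence. Provides hand-crafted protein
    feature encoders (PSSM-400 with BLOSUM62 fallback,
    composition-transition-distribution, conjoint triad, pseudo amino acid
    composition), a loader for precomputed protein language-model embeddings,
    a GRU-based classifier with a batch-normalized discriminator head trained
    with a class-weighted binary cross-entropy, four training/transfer
    strategies (direct training, supervised pre-training, a pooled general
    model, and two-stage pretrain-then-fine-tune transfer), an
    imbalance-aware metric suite (balanced accuracy, Matthews correlation,
    ROC AUC, precision-recall AUC), temperature-scaling probability
    calibration, and a genome-scale screening stage with confidence-binned
    summaries. A synthetic-data module generates domain-shifted labeled
    embedding datasets, composition-biased toy sequences and random PSSM
    profiles so that the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
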