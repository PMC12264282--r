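Package: semigraph
Title: Robust Semi-Supervised Multi-Label Node Classification on Sparse Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-supervised multi-label node classification for sparse,
    homophilous graphs such as diagnostic-code (ICD-like) networks. Implements
    stochastic DropNode feature augmentation with mixed-order adjacency
    propagation, residual embeddings with a closed-form fixed point,
    consistency-regularized training with temperature sharpening,
    reinforcement-learning construction of a label dependency graph via
    REINFORCE, and Wasserstein-1 adversarial domain adaptation. Ships a
    synthetic-data generator for taxonomy-structured multi-label graphs,
    domain-shifted twins and random-edge attacks, together with evaluation
    metrics (macro/micro AUC and F1, precision-at-k, accuracy), plain-text
    graph IO and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
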