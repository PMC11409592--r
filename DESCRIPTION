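Package: fastmpn
Title: Fast Message Passing Networks for Graph-of-Words Text Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a fast message passing graph convolutional classifier
    over graph-of-words representations of free-text documents, with trainable
    node embeddings, globally shared trainable edge weights, and multi-task
    softmax output heads. Message aggregation is available in a reference
    dimension-wise maximum mode and in dense and sparse weighted-sum modes; the
    sparse mode uses gather-scatter aggregation over flattened edge lists.
    Includes mini-batched multi-task training with hand-derived gradients and
    adaptive moment estimation, micro- and macro-averaged F1 evaluation with a
    12-score aggregate, a synthetic pathology-report corpus generator that
    emulates the linguistic variability and severe class imbalance of cancer
    registry free text, and command-line entry points for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
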