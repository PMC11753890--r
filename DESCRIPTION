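Package: targetclp
Title: Multi-View Protein Feature Engineering and Classification for Clathrin Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-engineering and classification toolkit for predicting
    clathrin proteins from sequence. Implements completed local binary
    pattern (CLBP) texture descriptors of position-specific scoring
    matrices (PSSM-CLBP) and of residue-wise energy contact matrices
    (RECM-CLBP), composition/transition/distribution physicochemical
    descriptors (QLC), pooled protein language-model embeddings,
    differential-evolution weighted multi-view feature integration,
    binary tree-growth feature selection, and a self-normalizing
    bidirectional LSTM classifier, together with stratified
    cross-validation and the standard binary-classification metrics.
    Seeded synthetic-data generators emulate every input so the full
    pipeline runs without external databases or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
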