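Package: paratopeR
Title: Chain-Aware Sequence-Based Antibody Paratope Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Residue-level prediction of antibody paratopes (antigen-contacting
    residues) from variable-domain amino-acid sequences alone. Implements a
    bidirectional LSTM followed by a length-preserving 1D convolution and a
    per-residue sigmoid classifier, trained with a masked, class-weighted
    binary cross-entropy loss to handle the ~10% positive-residue imbalance.
    Includes complex-level blind splitting and stratified grouped five-fold
    cross-validation that keeps paired heavy and light chains together, an
    imbalance-robust evaluation panel (ROC AUC, PR AUC, accuracy, precision,
    recall, F1, balanced accuracy, MCC), a configuration sweep over encodings,
    chain regimes and kernel sizes, a synthetic paired-chain data generator
    with planted binding motifs, and a scriptable command-line workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
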