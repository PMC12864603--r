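Package: aopred
Title: Multi-View Antioxidant Peptide Classification with xLSTM and
    Message Passing Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts antioxidant activity of short peptides (2-50 residues)
    by fusing two learned views of each molecule: a 128-dimensional sequence
    embedding from a stack of extended-LSTM (sLSTM/mLSTM) blocks and a
    128-dimensional molecular-graph embedding from a degree-conditioned
    message passing neural network built on the peptide's SMILES topology.
    Includes peptide dataset readers (FASTA and delimited tables), a
    synthetic benchmark generator with controllable composition bias,
    deterministic SMILES construction for linear peptides, training with
    Adam and binary cross-entropy, stratified k-fold cross-validation,
    Matthews-correlation-based evaluation, length-stratified ablation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineOB,
    ChemmineR,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
SystemRequirements: OpenBabel (obabel) for SMILES canonicalization
Config/testthat/edition: 3
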