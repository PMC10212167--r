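Package: mutTCN
Title: Per-Nucleotide Mutation Detection with Temporal Convolutional Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequence-labelling toolkit that classifies every nucleotide of a
    DNA sequence as normal, SNV, insertion or deletion. Sequences are mapped to
    integer k-mer codes (integer, 2-mer or 3-mer tables), cut into overlapping
    fixed-length windows, one-hot expanded and fed to a temporal convolutional
    network (TCN): stacked residual blocks of weight-normalised dilated causal
    convolutions with ReLU and spatial dropout, a 1x1 convolution and a
    position-shared softmax head. Includes a seeded mutation simulator with
    exact ground-truth labels (reference panels, mutated samples and short
    reads), stratified train/test splitting with random under-sampling,
    single-threaded reproducible training, per-class precision/recall/F1 and
    one-vs-rest ROC/AUC evaluation, and extraction of mutation calls (type and
    1-based index) from predicted label sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'utils.R'
    'encoding.R'
    'simulator.R'
    'dataset-io.R'
    'windows.R'
    'tcn-layers.R'
    'tcn-model.R'
    'training.R'
    'evaluation.R'
    'pipeline.R'
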