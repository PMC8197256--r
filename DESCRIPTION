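Package: tfcrnn
Title: Transcription Factor Binding Site Prediction with k-mer Embeddings
    and a Convolutional Recurrent Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts transcription factor binding from fixed-length DNA
    sequence. A sequence is combined with its complement, reverse and
    reverse-complement into a single four-strand string, segmented into
    overlapping k-mers, embedded with a corpus-trained continuous
    bag-of-words (CBOW) word2vec model, and classified by a hybrid
    one-dimensional convolutional / bidirectional LSTM network with a
    sigmoid head. Includes GC- and length-matched negative-set
    construction from ranked ChIP-seq peaks, stratified three-fold
    cross-validation with an inner validation split, ROC/PR/F1 metrics,
    ablation grids (k, stride, featurizer, input mode, architecture),
    and a motif-implantation simulator for fully synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
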