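#' Tokenized k-mer corpus
#'
#' An ordered collection of k-mer "sentences", one per source sequence,
#' carrying the tokenization provenance (k, stride). Sentences are
#' character vectors of k-mer tokens in source order.
#'
#' @slot sentences list of character vectors, one per sequence.
#' @slot k integer, k-mer length.
#' @slot s integer, stride between successive k-mer windows.
#' @slot ids character, source sequence identifiers.
#' @export
setClass("KmerCorpus",
  representation(sentences = "list", k = "integer", s = "integer",
                 ids = "character"))

setValidity("KmerCorpus", function(object) {
  if (length(object@sentences) != length(object@ids))
    return("number of sentences and ids differ")
  if (object@k < 1L || object@s < 1L)
    return("k and s must be >= 1")
  bad <- vapply(object@sentences,
                function(x) !is.character(x) || any(nchar(x) != object@k),
                logical(1))
  if (any(bad))
    return(sprintf("sentence %d contains tokens of length != k", which(bad)[1]))
  TRUE
})

#' Distributed k-mer embedding model
#'
#' A vocabulary of k-mer tokens mapped to fixed-dimension real vectors,
#' trained by CBOW word2vec (or an identity matrix for the one-hot
#' baseline), plus training metadata.
#'
#' @slot vectors numeric matrix (vocabulary x d), rownames are tokens.
#' @slot k integer, k-mer length of the vocabulary.
#' @slot s integer, tokenization stride used for the training corpus.
#' @slot meta list of training metadata (window, epochs, seed, minCount,
#'   negative, alpha, featurizer tag).
#' @export
setClass("EmbeddingModel",
  representation(vectors = "matrix", k = "integer", s = "integer",
                 meta = "list"))

setValidity("EmbeddingModel", function(object) {
  if (ncol(object@vectors) < 1L) return("embedding dimension must be >= 1")
  if (is.null(rownames(object@vectors))) return("vectors must have token rownames")
  if (any(nchar(rownames(object@vectors)) != object@k))
    return("all vocabulary tokens must have length k")
  if (!all(is.finite(object@vectors))) return("vectors must be finite")
  TRUE
})

#' Labeled sequence dataset
#'
#' Fixed-length DNA sequences with binary bound/unbound labels, as used
#' for training and evaluating the classifier. All sequences share one
#' length; the observed negative:positive ratio is recorded.
#'
#' @slot sequences [Biostrings::DNAStringSet] with unique names.
#' @slot labels integer vector of 0/1 labels, parallel to `sequences`.
#' @slot ratio numeric, configured negatives per positive.
#' @slot meta list of provenance (simulation truth table, seeds, ...).
#' @export
setClass("LabeledSeqSet",
  representation(sequences = "DNAStringSet", labels = "integer",
                 ratio = "numeric", meta = "list"))

setValidity("LabeledSeqSet", function(object) {
  n <- length(object@sequences)
  if (length(object@labels) != n) return("labels and sequences differ in length")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0 or 1")
  if (n > 0 && length(unique(width(object@sequences))) != 1L)
    return("all sequences must share one length")
  nm <- names(object@sequences)
  if (n > 0 && (is.null(nm) || anyDuplicated(nm)))
    return("sequences must carry unique names")
  TRUE
})

#' Cross-validation fold assignment
#'
#' A stratified partition of a dataset into folds, plus one validation
#' mask per held-out fold: when fold f is the test fold, the records
#' flagged in `valMask[[f]]` (a subset of the remaining folds) form the
#' validation set used for model selection.
#'
#' @slot fold integer vector, fold id (1..nFolds) per record.
#' @slot valMask list of logical vectors, one per fold.
#' @slot nFolds integer.
#' @slot seed integer seed the assignment was drawn with.
#' @export
setClass("FoldSplit",
  representation(fold = "integer", valMask = "list", nFolds = "integer",
                 seed = "integer"))

setValidity("FoldSplit", function(object) {
  if (!all(object@fold %in% seq_len(object@nFolds)))
    return("fold ids outside 1..nFolds")
  if (length(object@valMask) != object@nFolds)
    return("one validation mask per fold required")
  for (f in seq_len(object@nFolds)) {
    vm <- object@valMask[[f]]
    if (length(vm) != length(object@fold))
      return("validation masks must be parallel to fold vector")
    if (any(vm & object@fold == f))
      return("validation mask overlaps its own test fold")
  }
  TRUE
})

#' Network architecture configuration
#'
#' Hyperparameters of the convolutional/recurrent classifier. Defaults
#' are the recommended values of the underlying study: 3 convolution
#' modules of 16 channels with kernel size 3 and max-pool window 2,
#' a bi-LSTM with 16 units per direction, a 32-unit fully-connected
#' layer with dropout 0.1, and a sigmoid output.
#'
#' @slot nConv integer, number of convolution modules.
#' @slot convChannels integer, channels per convolution module.
#' @slot kernelSize integer, 1-D convolution kernel width (odd).
#' @slot poolWindow integer, max-pool window (= stride, non-overlapping).
#' @slot lstmUnits integer, LSTM units per direction.
#' @slot fcHidden integer, width of the first fully-connected layer.
#' @slot dropout numeric in [0,1), dropout rate between the FC layers.
#' @slot batchNorm logical, batch normalization inside conv modules.
#' @slot arch character, one of "hybrid", "cnn_only", "rnn_only".
#' @slot rnnHead character, how the bi-LSTM output feeds the FC head:
#'   "maxpool" (max over time of each hidden unit, position-invariant)
#'   or "flatten" (full output sequence flattened).
#' @slot seed integer, weight-initialization seed.
#' @export
setClass("ModelConfig",
  representation(nConv = "integer", convChannels = "integer",
                 kernelSize = "integer", poolWindow = "integer",
                 lstmUnits = "integer", fcHidden = "integer",
                 dropout = "numeric", batchNorm = "logical",
                 arch = "character", rnnHead = "character",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  sizes <- c(object@nConv, object@convChannels, object@kernelSize,
             object@poolWindow, object@lstmUnits, object@fcHidden)
  if (any(sizes < 1L)) return("all sizes must be positive integers")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (!object@arch %in% c("hybrid", "cnn_only", "rnn_only"))
    return("arch must be hybrid, cnn_only or rnn_only")
  if (!object@rnnHead %in% c("maxpool", "flatten"))
    return("rnnHead must be maxpool or flatten")
  if (object@kernelSize %% 2L == 0L)
    return("kernelSize must be odd (length-preserving zero padding)")
  TRUE
})

#' Optimizer configuration
#'
#' @slot epochs integer, training epochs (default 20).
#' @slot batchSize integer (default 64).
#' @slot learningRate numeric (default 1e-3).
#' @slot optimizer character, "adam" or "adadelta".
#' @slot plateauDecay logical, halve the learning rate when validation
#'   ROC AUC stalls (off by default).
#' @slot patience integer, epochs without improvement before decay.
#' @slot factor numeric, decay multiplier.
#' @slot seed integer, seed for shuffling and dropout.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", optimizer = "character",
                 plateauDecay = "logical", patience = "integer",
                 factor = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (!object@optimizer %in% c("adam", "adadelta"))
    return("optimizer must be adam or adadelta")
  TRUE
})

#' Fitted (or freshly initialized) classifier
#'
#' @slot config [ModelConfig-class].
#' @slot inputLen integer, token count per record the network expects.
#' @slot inputDim integer, feature dimension per token.
#' @slot params named list of weight matrices/vectors.
#' @slot bnState named list of running batch-norm statistics.
#' @slot history data.frame with one row per trained epoch
#'   (epoch, loss, valAUC, lr).
#' @slot bestEpoch integer, epoch whose parameters are stored.
#' @slot embedMeta list describing the featurizer the model was trained on.
#' @export
setClass("TrainedModel",
  representation(config = "ModelConfig", inputLen = "integer",
                 inputDim = "integer", params = "list", bnState = "list",
                 history = "data.frame", bestEpoch = "integer",
                 embedMeta = "list"))

#' Binary-classification metrics report
#'
#' @slot rocAUC,prAUC,f1 numeric metrics in \[0,1\].
#' @slot threshold numeric, score threshold used for F1.
#' @slot nPos,nNeg integer class counts.
#' @export
setClass("MetricsReport",
  representation(rocAUC = "numeric", prAUC = "numeric", f1 = "numeric",
                 threshold = "numeric", nPos = "integer", nNeg = "integer"))

setValidity("MetricsReport", function(object) {
  m <- c(object@rocAUC, object@prAUC, object@f1)
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("metrics must lie in [0,1]")
  if (object@nPos < 1L || object@nNeg < 1L)
    return("both classes must be represented")
  TRUE
})

#' Position weight matrix motif model
#'
#' @slot pwm numeric matrix (motif length x 4), columns A, C, G, T; each
#'   row a probability distribution.
#' @slot name character motif label.
#' @export
setClass("MotifModel", representation(pwm = "matrix", name = "character"))

setValidity("MotifModel", function(object) {
  if (ncol(object@pwm) != 4L) return("pwm must have 4 columns (A, C, G, T)")
  if (any(object@pwm < 0)) return("pwm entries must be non-negative")
  if (any(abs(rowSums(object@pwm) - 1) > 1e-9))
    return("each pwm row must sum to 1")
  if (!identical(colnames(object@pwm), c("A", "C", "G", "T")))
    return('pwm columns must be named "A","C","G","T"')
  TRUE
})
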