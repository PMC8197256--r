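#' @rdname KmerCorpus-class
#' @param x a \code{KmerCorpus} or \code{EmbeddingModel}.
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @rdname KmerCorpus-class
#' @export
setGeneric("strideSize", function(x) standardGeneric("strideSize"))
#' @rdname KmerCorpus-class
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))

#' @rdname EmbeddingModel-class
#' @param x an \code{EmbeddingModel}.
#' @export
setGeneric("wordVectors", function(x) standardGeneric("wordVectors"))
#' @rdname EmbeddingModel-class
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
#' @rdname EmbeddingModel-class
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname LabeledSeqSet-class
#' @param x a \code{LabeledSeqSet}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname LabeledSeqSet-class
#' @param object,... passed to the \code{labels} generic.
#' @export
setGeneric("labels")

#' @rdname TrainedModel-class
#' @param x a \code{TrainedModel}.
#' @export
setGeneric("modelHistory", function(x) standardGeneric("modelHistory"))
#' @rdname TrainedModel-class
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

setMethod("kmerSize", "KmerCorpus", function(x) x@k)
setMethod("strideSize", "KmerCorpus", function(x) x@s)
setMethod("sentences", "KmerCorpus", function(x) setNames(x@sentences, x@ids))
setMethod("kmerSize", "EmbeddingModel", function(x) x@k)
setMethod("strideSize", "EmbeddingModel", function(x) x@s)
setMethod("wordVectors", "EmbeddingModel", function(x) x@vectors)
setMethod("embeddingDim", "EmbeddingModel", function(x) ncol(x@vectors))
setMethod("vocabulary", "EmbeddingModel", function(x) rownames(x@vectors))
setMethod("sequences", "LabeledSeqSet", function(x) x@sequences)
setMethod("labels", "LabeledSeqSet", function(object, ...) object@labels)
setMethod("modelHistory", "TrainedModel", function(x) x@history)
setMethod("modelConfigOf", "TrainedModel", function(x) x@config)

#' @rdname LabeledSeqSet-class
#' @aliases length,LabeledSeqSet-method
#' @export
setMethod("length", "LabeledSeqSet", function(x) length(x@sequences))

setMethod("show", "KmerCorpus", function(object) {
  cat(sprintf("KmerCorpus: %d sentences, k=%d, s=%d\n",
              length(object@sentences), object@k, object@s))
  if (length(object@sentences)) {
    n <- lengths(object@sentences)
    cat(sprintf("  tokens per sentence: %d..%d\n", min(n), max(n)))
  }
})

setMethod("show", "EmbeddingModel", function(object) {
  cat(sprintf("EmbeddingModel: |vocab|=%d, d=%d, k=%d, s=%d (%s)\n",
              nrow(object@vectors), ncol(object@vectors), object@k,
              object@s,
              if (is.null(object@meta$featurizer)) "cbow"
              else object@meta$featurizer))
})

setMethod("show", "LabeledSeqSet", function(object) {
  cat(sprintf("LabeledSeqSet: %d records (%d pos / %d neg), width %s bp\n",
              length(object@sequences), sum(object@labels == 1L),
              sum(object@labels == 0L),
              if (length(object@sequences)) width(object@sequences)[1] else "-"))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: %d records in %d folds (seed %d)\n",
              length(object@fold), object@nFolds, object@seed))
  print(table(fold = object@fold))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig [%s]: %d conv x %d ch (kernel %d, pool %d), LSTM %d/dir,\n  FC %d, dropout %.2f, batchNorm=%s, seed %d\n",
    object@arch, object@nConv, object@convChannels, object@kernelSize,
    object@poolWindow, object@lstmUnits, object@fcHidden, object@dropout,
    object@batchNorm, object@seed))
})

setMethod("show", "TrainedModel", function(object) {
  trained <- nrow(object@history) > 0
  cat(sprintf("TrainedModel (%s): input %d x %d, %s\n",
              object@config@arch, object@inputLen, object@inputDim,
              if (trained)
                sprintf("best epoch %d (val ROC AUC %.4f)", object@bestEpoch,
                        max(object@history$valAUC))
              else "untrained"))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: ROC AUC %.4f | PR AUC %.4f | F1 %.4f (thr %.2f; %d pos / %d neg)\n",
    object@rocAUC, object@prAUC, object@f1, object@threshold,
    object@nPos, object@nNeg))
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel '%s': %d positions, consensus %s\n", object@name,
              nrow(object@pwm),
              paste(colnames(object@pwm)[max.col(object@pwm)], collapse = "")))
})
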