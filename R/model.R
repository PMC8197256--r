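#' Create a network configuration
#'
#' Defaults follow the recommended hyperparameter set of the underlying
#' study (3 convolution modules, 16 channels, kernel 3, pool 2, 16
#' bi-LSTM units per direction, dropout 0.1). Batch normalization
#' inside the convolution modules is available (`batchNorm = TRUE`) but
#' off by default: the prose description of the architecture omits it,
#' and at desk scale it measurably hurts held-out ranking (see the
#' methods vignette).
#'
#' @param nConv number of convolution modules.
#' @param convChannels channels per module.
#' @param kernelSize 1-D kernel width (odd).
#' @param poolWindow max-pool window (stride equals window).
#' @param lstmUnits LSTM units per direction.
#' @param fcHidden width of the first fully-connected layer.
#' @param dropout dropout rate between the two FC layers.
#' @param batchNorm enable batch normalization.
#' @param arch "hybrid" (CNN then bi-LSTM), "cnn_only" (global max pool
#'   head) or "rnn_only" (bi-LSTM directly on the embedded input).
#' @param rnnHead bi-LSTM-to-head connection: "maxpool" (default; max
#'   over time of every hidden unit, position-invariant) or "flatten"
#'   (full output sequence into the first FC layer).
#' @param seed weight-initialization seed.
#' @return a [ModelConfig-class].
#' @export
modelConfig <- function(nConv = 3L, convChannels = 16L, kernelSize = 3L,
                        poolWindow = 2L, lstmUnits = 16L, fcHidden = 32L,
                        dropout = 0.1, batchNorm = FALSE,
                        arch = c("hybrid", "cnn_only", "rnn_only"),
                        rnnHead = c("maxpool", "flatten"),
                        seed = 1L) {
  arch <- match.arg(arch)
  rnnHead <- match.arg(rnnHead)
  new("ModelConfig", nConv = as.integer(nConv),
      convChannels = as.integer(convChannels),
      kernelSize = as.integer(kernelSize),
      poolWindow = as.integer(poolWindow),
      lstmUnits = as.integer(lstmUnits), fcHidden = as.integer(fcHidden),
      dropout = dropout, batchNorm = batchNorm, arch = arch,
      rnnHead = rnnHead, seed = as.integer(seed))
}

.cfgList <- function(config) {
  list(nConv = config@nConv, convChannels = config@convChannels,
       kernelSize = config@kernelSize, poolWindow = config@poolWindow,
       lstmUnits = config@lstmUnits, fcHidden = config@fcHidden,
       batchNorm = config@batchNorm, arch = config@arch,
       rnnHead = config@rnnHead)
}

.xavier <- function(nout, nin, fanIn = nin, fanOut = nout) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nout * nin, -lim, lim), nrow = nout, ncol = nin)
}

# sequence length after the conv stack (floor-halving per pool)
.pooledLength <- function(inputLen, config) {
  L <- inputLen
  if (config@arch != "rnn_only")
    for (i in seq_len(config@nConv)) L <- L %/% config@poolWindow
  L
}

#' Build an untrained classifier
#'
#' Assembles the configured architecture and initializes all weights
#' with Xavier-uniform draws (biases zero), seeded by `config@seed`.
#' Each convolution module is a length-preserving 1-D convolution,
#' ReLU, optional batch normalization and non-overlapping max-pooling,
#' so an input of `inputLen` tokens reaches the recurrent module at
#' `floor(inputLen / poolWindow^nConv)` steps (798 -> 399 -> 199 -> 99
#' at the defaults). The bi-LSTM output feeds two fully-connected
#' layers (one dropout layer, sigmoid output) through the configured
#' `rnnHead`: position-invariant max-over-time pooling of every hidden
#' unit (default), or the full output sequence flattened so every
#' position keeps its own head weights.
#'
#' @param config a [ModelConfig-class].
#' @param inputLen tokens per record.
#' @param inputDim features per token (embedding dimension).
#' @return an untrained [TrainedModel-class].
#' @export
buildModel <- function(config, inputLen, inputDim) {
  stopifnot(is(config, "ModelConfig"))
  inputLen <- as.integer(inputLen); inputDim <- as.integer(inputDim)
  minLen <- if (config@arch == "rnn_only") 1L
            else config@poolWindow^config@nConv
  if (inputLen < minLen)
    stop(sprintf("input length %d is below the minimum %d required by %d pooling layer(s) of window %d",
                 inputLen, minLen, config@nConv, config@poolWindow))
  set.seed(config@seed)
  params <- list()
  bnState <- list()
  C <- config@convChannels; k <- config@kernelSize; H <- config@lstmUnits
  if (config@arch != "rnn_only") {
    cin <- inputDim
    for (i in seq_len(config@nConv)) {
      params[[sprintf("conv%d_W", i)]] <-
        .xavier(C, cin * k, fanIn = cin * k, fanOut = C * k)
      params[[sprintf("conv%d_b", i)]] <- numeric(C)
      if (config@batchNorm) {
        params[[sprintf("bn%d_gamma", i)]] <- rep(1, C)
        params[[sprintf("bn%d_beta", i)]] <- numeric(C)
        bnState[[sprintf("bn%d_mean", i)]] <- numeric(C)
        bnState[[sprintf("bn%d_var", i)]] <- rep(1, C)
      }
      cin <- C
    }
  }
  if (config@arch != "cnn_only") {
    dIn <- if (config@arch == "rnn_only") inputDim else C
    for (dir in c("fw", "bw")) {
      params[[sprintf("lstm_%s_W", dir)]] <- .xavier(4L * H, dIn)
      params[[sprintf("lstm_%s_U", dir)]] <- .xavier(4L * H, H)
      params[[sprintf("lstm_%s_b", dir)]] <- numeric(4L * H)
    }
  }
  featDim <- if (config@arch == "cnn_only") C
             else if (config@rnnHead == "maxpool") 2L * H
             else 2L * H * .pooledLength(inputLen, config)
  params$fc1_W <- .xavier(config@fcHidden, featDim)
  params$fc1_b <- numeric(config@fcHidden)
  params$fc2_W <- .xavier(1L, config@fcHidden)
  params$fc2_b <- numeric(1L)
  new("TrainedModel", config = config, inputLen = inputLen,
      inputDim = inputDim, params = params, bnState = bnState,
      history = data.frame(), bestEpoch = 0L, embedMeta = list())
}

#' Total trainable parameter count
#'
#' @param model a [TrainedModel-class].
#' @return integer.
#' @export
nParams <- function(model) sum(vapply(model@params, length, integer(1)))

#' One bi-LSTM cell step (single direction)
#'
#' The gated recurrence: forget, input and output gates are sigmoids of
#' affine maps of the input and previous hidden state; the cell state
#' mixes its past through the forget gate with a tanh candidate through
#' the input gate; the hidden state is the output gate times tanh of
#' the cell state. Pure-R reference used to verify the compiled
#' training path.
#'
#' @param x input vector at this position.
#' @param hPrev,cPrev previous hidden and cell state (length H).
#' @param params list with matrices `Wf, Wi, Wc, Wo` (H x d_in),
#'   `Uf, Ui, Uc, Uo` (H x H) and biases `bf, bi, bc, bo` (length H).
#' @return list with `h` and `c`, both length H.
#' @examples
#' H <- 2; d <- 3
#' z <- function(...) matrix(0, ...)
#' p <- list(Wf = z(H, d), Wi = z(H, d), Wc = z(H, d), Wo = z(H, d),
#'           Uf = z(H, H), Ui = z(H, H), Uc = z(H, H), Uo = z(H, H),
#'           bf = numeric(H), bi = numeric(H), bc = numeric(H),
#'           bo = numeric(H))
#' st <- biLstmStep(rnorm(d), numeric(H), c(1, -1), p)
#' st$c  # 0.5 * cPrev
#' @export
biLstmStep <- function(x, hPrev, cPrev, params) {
  p <- params
  dims <- vapply(p[c("Wf", "Wi", "Wc", "Wo")], ncol, integer(1))
  if (any(dims != length(x))) stop("shape mismatch between x and W matrices")
  H <- length(hPrev)
  if (any(vapply(p[c("Uf", "Ui", "Uc", "Uo")], ncol, integer(1)) != H))
    stop("shape mismatch between hPrev and U matrices")
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(as.vector(p$Wf %*% x + p$Uf %*% hPrev) + p$bf)
  i <- sig(as.vector(p$Wi %*% x + p$Ui %*% hPrev) + p$bi)
  g <- tanh(as.vector(p$Wc %*% x + p$Uc %*% hPrev) + p$bc)
  o <- sig(as.vector(p$Wo %*% x + p$Uo %*% hPrev) + p$bo)
  cNew <- f * cPrev + i * g
  list(h = o * tanh(cNew), c = cNew)
}

.asBatchCube <- function(x, inputLen, inputDim) {
  if (is.matrix(x)) x <- list(x)
  if (is.list(x)) {
    arr <- array(0, dim = c(inputLen, inputDim, length(x)))
    for (j in seq_along(x)) {
      m <- x[[j]]
      if (nrow(m) != inputLen || ncol(m) != inputDim)
        stop(sprintf("matrix %d is %d x %d but the model expects %d x %d",
                     j, nrow(m), ncol(m), inputLen, inputDim))
      arr[, , j] <- m
    }
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1] != inputLen || dim(x)[2] != inputDim)
      stop(sprintf("array is %d x %d but the model expects %d x %d",
                   dim(x)[1], dim(x)[2], inputLen, inputDim))
    return(x)
  }
  stop("x must be a matrix, a list of matrices or a 3-D array")
}

#' Predict binding probabilities
#'
#' Deterministic evaluation-mode forward pass (dropout off, batch-norm
#' running statistics); one probability in (0, 1) per record.
#'
#' @param model a [TrainedModel-class].
#' @param x a single `tokens x d` matrix, a list of them, or a 3-D
#'   array `(tokens, d, records)`.
#' @param batchSize records per forward pass.
#' @return numeric vector of probabilities.
#' @export
predictProb <- function(model, x, batchSize = 64L) {
  arr <- .asBatchCube(x, model@inputLen, model@inputDim)
  n <- dim(arr)[3]
  out <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    out[b] <- nn_predict_cpp(arr[, , b, drop = FALSE], model@params,
                             model@bnState, .cfgList(model@config))
  }
  out
}

.configHash <- function(config, inputLen, inputDim) {
  paste(config@arch, config@rnnHead, config@nConv, config@convChannels, config@kernelSize,
        config@poolWindow, config@lstmUnits, config@fcHidden,
        config@batchNorm, inputLen, inputDim, sep = "|")
}

#' Save/load a model checkpoint
#'
#' Single-file checkpoint holding parameters, batch-norm state, the
#' full configuration and a configuration hash. `loadModel` refuses to
#' load when an expected configuration is supplied and its hash does
#' not match the checkpoint.
#'
#' @param model a [TrainedModel-class].
#' @param path checkpoint file.
#' @param config optional [ModelConfig-class] the caller expects.
#' @return `loadModel` returns the [TrainedModel-class].
#' @export
saveModel <- function(model, path) {
  obj <- list(model = model,
              hash = .configHash(model@config, model@inputLen,
                                 model@inputDim),
              package = "tfcrnn",
              version = as.character(utils::packageVersion("tfcrnn")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path, config = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$hash)) stop("not a model checkpoint")
  if (!is.null(config)) {
    m <- obj$model
    if (!identical(.configHash(config, m@inputLen, m@inputDim), obj$hash))
      stop("checkpoint configuration does not match the expected configuration")
  }
  obj$model
}
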