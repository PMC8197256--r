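#' Create a training configuration
#'
#' Defaults follow the study protocol: 20 epochs, batch size 64,
#' learning rate 1e-3, Adam, binary cross-entropy loss (fixed). Adam's
#' own adaptive moments provide the dynamic per-epoch adjustment; an
#' optional plateau decay of the learning rate is off by default.
#'
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param learningRate initial learning rate.
#' @param optimizer "adam" or "adadelta".
#' @param plateauDecay halve `learningRate` after `patience` epochs
#'   without validation improvement.
#' @param patience epochs of patience for the decay.
#' @param factor decay multiplier.
#' @param seed RNG seed for shuffling and dropout.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 20L, batchSize = 64L, learningRate = 1e-3,
                        optimizer = c("adam", "adadelta"),
                        plateauDecay = FALSE, patience = 3L, factor = 0.5,
                        seed = 1L) {
  optimizer <- match.arg(optimizer)
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      optimizer = optimizer, plateauDecay = plateauDecay,
      patience = as.integer(patience), factor = factor,
      seed = as.integer(seed))
}

# --- featurized batch access -------------------------------------------------

# x: integer id matrix (records x tokens) + augmented vector matrix, or
# list of matrices / 3-D array. Returns fetch(idx) -> cube.
.makeFetcher <- function(x, embedding, inputLen, inputDim) {
  if (!is.null(embedding)) {
    E <- if (is(embedding, "EmbeddingModel")) .augmentedVectors(embedding)
         else embedding
    stopifnot(is.matrix(x), ncol(x) == inputLen, ncol(E) == inputDim)
    if (max(x) > nrow(E)) stop("token id exceeds embedding table")
    force(E)
    n <- nrow(x)
    fetch <- function(idx) {
      arr <- array(0, dim = c(inputLen, inputDim, length(idx)))
      for (j in seq_along(idx)) arr[, , j] <- E[x[idx[j], ], , drop = FALSE]
      arr
    }
    return(list(fetch = fetch, n = n))
  }
  if (is.list(x) && !is.array(x)) {
    n <- length(x)
    fetch <- function(idx) {
      arr <- array(0, dim = c(inputLen, inputDim, length(idx)))
      for (j in seq_along(idx)) arr[, , j] <- x[[idx[j]]]
      arr
    }
    return(list(fetch = fetch, n = n))
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  list(fetch = function(idx) x[, , idx, drop = FALSE], n = dim(x)[3])
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.adadeltaInit <- function(params)
  list(g2 = lapply(params, function(p) p * 0),
       dx2 = lapply(params, function(p) p * 0))

.adadeltaStep <- function(params, grads, state, rho = 0.95, eps = 1e-6) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$g2[[nm]] <- rho * state$g2[[nm]] + (1 - rho) * g^2
    dx <- -sqrt(state$dx2[[nm]] + eps) / sqrt(state$g2[[nm]] + eps) * g
    state$dx2[[nm]] <- rho * state$dx2[[nm]] + (1 - rho) * dx^2
    params[[nm]] <- params[[nm]] + dx
  }
  list(params = params, state = state)
}

.predictInternal <- function(params, bnState, cfg, fetch, n, batchSize) {
  out <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batchSize)))
    out[b] <- nn_predict_cpp(fetch(b), params, bnState, cfg)
  out
}

#' Fit the classifier
#'
#' Minimizes binary cross-entropy with the configured optimizer,
#' recording validation ROC AUC after every epoch; the returned
#' parameters are those of the epoch with the highest validation ROC
#' AUC, not the last. All stochastic pieces (shuffling, dropout masks)
#' flow from `trainCfg@seed`, so a rerun reproduces the fit exactly.
#'
#' @param model an untrained (or warm) [TrainedModel-class].
#' @param x,y training inputs and 0/1 labels. `x` is either an integer
#'   token-id matrix (with `embedding` supplied), a list of
#'   `tokens x d` matrices, or a 3-D array.
#' @param xVal,yVal validation inputs/labels, disjoint from training;
#'   both classes must be present.
#' @param trainCfg a [TrainConfig-class].
#' @param embedding an [EmbeddingModel-class] (or pre-augmented vector
#'   matrix with a terminal zero row) when `x` holds token ids.
#' @param verbose print per-epoch progress.
#' @return the fitted [TrainedModel-class] with `history` and
#'   `bestEpoch` populated.
#' @export
fitModel <- function(model, x, y, xVal, yVal, trainCfg = trainConfig(),
                     embedding = NULL, verbose = FALSE) {
  stopifnot(is(model, "TrainedModel"), is(trainCfg, "TrainConfig"))
  y <- as.numeric(y); yVal <- as.integer(yVal)
  if (length(unique(yVal)) < 2L)
    stop("validation set contains a single class: ROC AUC is undefined")
  tr <- .makeFetcher(x, embedding, model@inputLen, model@inputDim)
  va <- .makeFetcher(xVal, embedding, model@inputLen, model@inputDim)
  if (tr$n != length(y)) stop("x and y differ in length")
  cfg <- .cfgList(model@config)
  params <- model@params
  bnState <- model@bnState
  p <- model@config@dropout
  fcH <- model@config@fcHidden
  opt <- trainCfg@optimizer
  state <- if (opt == "adam") .adamInit(params) else .adadeltaInit(params)
  lr <- trainCfg@learningRate
  momentum <- 0.1

  set.seed(trainCfg@seed)
  best <- list(auc = -Inf, epoch = 0L, params = params, bnState = bnState)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     valAUC = numeric(), lr = numeric())
  sinceBest <- 0L
  for (ep in seq_len(trainCfg@epochs)) {
    ord <- sample(tr$n)
    lossSum <- 0
    for (b in split(ord, ceiling(seq_along(ord) / trainCfg@batchSize))) {
      X <- tr$fetch(b)
      nb <- length(b)
      mask <- if (p > 0)
        matrix((runif(fcH * nb) >= p) / (1 - p), fcH, nb)
      else matrix(1, fcH, nb)
      res <- nn_fwbw(X, y[b], params, cfg, mask)
      for (nm in names(res$bnBatch))
        bnState[[nm]] <- (1 - momentum) * bnState[[nm]] +
          momentum * res$bnBatch[[nm]]
      upd <- if (opt == "adam") .adamStep(params, res$grads, state, lr)
             else .adadeltaStep(params, res$grads, state)
      params <- upd$params; state <- upd$state
      lossSum <- lossSum + res$loss * nb
    }
    valProbs <- .predictInternal(params, bnState, cfg, va$fetch, va$n,
                                 trainCfg@batchSize)
    vauc <- rocAUC(yVal, valProbs)
    hist <- rbind(hist, data.frame(epoch = ep, loss = lossSum / tr$n,
                                   valAUC = vauc, lr = lr))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val ROC AUC %.4f", ep,
                      lossSum / tr$n, vauc))
    if (vauc > best$auc) {
      best <- list(auc = vauc, epoch = ep, params = params,
                   bnState = bnState)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (trainCfg@plateauDecay && sinceBest >= trainCfg@patience) {
        lr <- lr * trainCfg@factor
        sinceBest <- 0L
      }
    }
  }
  initialize(model, params = best$params, bnState = best$bnState,
             history = hist, bestEpoch = best$epoch)
}

#' @rdname KmerCorpus-class
#' @param i index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "KmerCorpus", function(x, i, j, ..., drop = FALSE) {
  new("KmerCorpus", sentences = x@sentences[i], k = x@k, s = x@s,
      ids = x@ids[i])
})

# crop token-id matrix to a centered window (used to keep rnn_only
# ablation cells affordable; documented, not hidden)
.cropTokens <- function(ids, maxTokens) {
  if (is.null(maxTokens) || ncol(ids) <= maxTokens) return(ids)
  off <- (ncol(ids) - maxTokens) %/% 2L
  ids[, (off + 1L):(off + maxTokens), drop = FALSE]
}

#' Cross-validated training and evaluation
#'
#' One fit per fold: the held-out fold is the test set, the validation
#' mask of that fold drives model selection, and the remaining records
#' are the training set. By default the CBOW embedding is retrained on
#' each fold's non-test portion only, so no test token statistics leak
#' into the featurizer; `perFoldEmbedding = FALSE` trains a single
#' embedding on the whole corpus instead. The final report is the
#' unweighted mean of the per-fold metrics; per-fold reports are
#' retained.
#'
#' @param dataset a [LabeledSeqSet-class].
#' @param folds a [FoldSplit-class]; defaults to
#'   `splitFolds(dataset, seed = trainCfg@seed)`.
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param k,s k-mer length and stride.
#' @param combined use the four-strand combined sequence (default) or
#'   the raw sequence.
#' @param featurizer "cbow" or "onehot".
#' @param embedDim,embedWindow,embedEpochs CBOW hyperparameters.
#' @param perFoldEmbedding retrain the embedding per fold (default).
#' @param maxTokens optional centered crop of the token sequence
#'   (affordability valve for `rnn_only`).
#' @param verbose print progress.
#' @return list with `perFold` (list of [MetricsReport-class]), `mean`
#'   (averaged [MetricsReport-class]), `folds`, and `models`.
#' @export
crossValidate <- function(dataset, folds = NULL, modelCfg = modelConfig(),
                          trainCfg = trainConfig(), k = 3L, s = 1L,
                          combined = TRUE,
                          featurizer = c("cbow", "onehot"),
                          embedDim = 100L, embedWindow = 5L,
                          embedEpochs = 10L, perFoldEmbedding = TRUE,
                          maxTokens = NULL, verbose = FALSE) {
  featurizer <- match.arg(featurizer)
  stopifnot(is(dataset, "LabeledSeqSet"))
  if (is.null(folds)) folds <- splitFolds(dataset, seed = trainCfg@seed)
  y <- dataset@labels
  corp <- buildCorpus(sequences(dataset), k = k, s = s, combined = combined)
  globalEmb <- NULL
  if (featurizer == "onehot") {
    globalEmb <- oneHotModel(k = k, s = s)
  } else if (!perFoldEmbedding) {
    globalEmb <- trainCBOW(corp, d = embedDim, window = embedWindow,
                           epochs = embedEpochs, seed = trainCfg@seed)
  }
  reports <- vector("list", folds@nFolds)
  models <- vector("list", folds@nFolds)
  for (f in seq_len(folds@nFolds)) {
    test <- folds@fold == f
    val <- folds@valMask[[f]]
    train <- !test & !val
    if (length(unique(y[test])) < 2L)
      stop("fold ", f, " contains a single class")
    emb <- if (!is.null(globalEmb)) globalEmb
           else trainCBOW(corp[!test], d = embedDim, window = embedWindow,
                          epochs = embedEpochs, seed = trainCfg@seed + f)
    ids <- .cropTokens(.tokenIdMatrix(corp, emb), maxTokens)
    mcfg <- initialize(modelCfg, seed = modelCfg@seed + f)
    model <- buildModel(mcfg, inputLen = ncol(ids),
                        inputDim = embeddingDim(emb))
    tcfg <- initialize(trainCfg, seed = trainCfg@seed + f)
    fit <- fitModel(model, ids[train, , drop = FALSE], y[train],
                    ids[val, , drop = FALSE], y[val], tcfg,
                    embedding = emb, verbose = verbose)
    fit@embedMeta <- c(emb@meta, list(k = k, s = s, combined = combined))
    probs <- predictProb(fit, .idsToArrayFetch(ids[test, , drop = FALSE], emb),
                         batchSize = trainCfg@batchSize)
    reports[[f]] <- evaluateScores(y[test], probs)
    models[[f]] <- fit
    if (verbose)
      message(sprintf("fold %d: test ROC AUC %.4f", f,
                      reports[[f]]@rocAUC))
  }
  tab <- metricsTable(reports)
  meanReport <- new("MetricsReport", rocAUC = mean(tab$rocAUC),
                    prAUC = mean(tab$prAUC), f1 = mean(tab$f1),
                    threshold = 0.5, nPos = sum(tab$nPos),
                    nNeg = sum(tab$nNeg))
  list(perFold = reports, mean = meanReport, folds = folds,
       models = models)
}

# materialize embedded matrices for a small id matrix
.idsToArrayFetch <- function(ids, embedding) {
  E <- .augmentedVectors(embedding)
  arr <- array(0, dim = c(ncol(ids), ncol(E), nrow(ids)))
  for (j in seq_len(nrow(ids))) arr[, , j] <- E[ids[j, ], , drop = FALSE]
  arr
}

#' Ablation grid runner
#'
#' Runs one [crossValidate()] per grid cell over combinations of
#' k-mer length, stride, featurizer (CBOW vs one-hot), input mode
#' (combined four-strand vs raw) and architecture (hybrid, CNN-only,
#' RNN-only). Infeasible cells (e.g. k larger than the sequence
#' length) are recorded as failed and the run continues.
#'
#' @param dataset a [LabeledSeqSet-class].
#' @param grid data.frame with any of the columns `k`, `stride`,
#'   `featurizer`, `inputMode` ("combined"/"raw"), `architecture`;
#'   missing columns fall back to the defaults.
#' @param modelCfg,trainCfg base configurations.
#' @param embedDim,maxTokens,... forwarded to [crossValidate()].
#' @param outFile optional TSV path for the results table.
#' @param verbose print progress.
#' @return data.frame: one row per cell with the averaged metrics,
#'   `status` ("ok"/"failed") and `message`.
#' @export
runAblation <- function(dataset, grid, modelCfg = modelConfig(),
                        trainCfg = trainConfig(), embedDim = 100L,
                        maxTokens = NULL, outFile = NULL, verbose = FALSE,
                        ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, , drop = FALSE]
    k <- if ("k" %in% names(cell)) cell$k else 3L
    s <- if ("stride" %in% names(cell)) cell$stride else 1L
    fz <- if ("featurizer" %in% names(cell)) as.character(cell$featurizer)
          else "cbow"
    im <- if ("inputMode" %in% names(cell)) as.character(cell$inputMode)
          else "combined"
    ar <- if ("architecture" %in% names(cell)) as.character(cell$architecture)
          else modelCfg@arch
    row <- data.frame(k = k, stride = s, featurizer = fz, inputMode = im,
                      architecture = ar, rocAUC = NA_real_,
                      prAUC = NA_real_, f1 = NA_real_, status = "ok",
                      message = "", stringsAsFactors = FALSE)
    out <- tryCatch({
      mc <- initialize(modelCfg, arch = ar)
      cv <- crossValidate(dataset, modelCfg = mc, trainCfg = trainCfg,
                          k = k, s = s, combined = (im == "combined"),
                          featurizer = fz, embedDim = embedDim,
                          maxTokens = maxTokens, verbose = FALSE, ...)
      row$rocAUC <- cv$mean@rocAUC
      row$prAUC <- cv$mean@prAUC
      row$f1 <- cv$mean@f1
      row
    }, error = function(e) {
      row$status <- "failed"
      row$message <- conditionMessage(e)
      row
    })
    if (verbose)
      message(sprintf("cell %d/%d [%s]: %s", i, nrow(grid), out$status,
                      if (out$status == "ok") sprintf("ROC AUC %.3f", out$rocAUC)
                      else out$message))
    res[[i]] <- out
  }
  tab <- do.call(rbind, res)
  if (!is.null(outFile))
    write.table(tab, outFile, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
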