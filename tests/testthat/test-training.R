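test_that("rocAUC matches the exhaustive pairwise oracle", {
  expect_equal(rocAUC(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(rocAUC(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(rocAUC(c(1, 1, 0, 0), c(0.8, 0.3, 0.5, 0.1)), 0.75)
  pairwise <- function(lab, sc) {
    ps <- sc[lab == 1]; ns <- sc[lab == 0]
    tot <- 0
    for (p in ps) for (q in ns)
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(ps) * length(ns))
  }
  set.seed(30)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    lab <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    sc <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_identical(rocAUC(lab, sc), pairwise(lab, sc))
  }
  expect_error(rocAUC(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("prAUC and f1 match confusion-matrix arithmetic on all 4-record labelings", {
  set.seed(31)
  sc <- c(0.9, 0.7, 0.4, 0.2)
  for (code in 1:14) {   # all labelings with >= 1 positive and >= 1 negative
    lab <- as.integer(intToBits(code)[1:4])
    if (sum(lab) %in% c(0, 4)) next
    expect_equal(prAUC(lab, sc), oraclePR(lab, sc))
    expect_equal(f1Score(lab, sc), oracleF1(lab, sc))
  }
  # tied scores enter thresholds together
  scT <- c(0.8, 0.8, 0.5, 0.5)
  lab <- c(1L, 0L, 1L, 0L)
  expect_equal(prAUC(lab, scT), oraclePR(lab, scT))
})

test_that("prAUC endpoints and random-score expectation behave", {
  expect_equal(prAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(prAUC(c(1, rep(0, 9)), c(0.99, runif(9, 0, 0.5))), 1.0)
  set.seed(32)
  lab <- rep(c(1L, 0L), c(300, 700))
  sc <- runif(1000)
  expect_lt(abs(prAUC(lab, sc) - 0.3), 0.05)
  expect_error(prAUC(rep(0L, 4), runif(4)), "no positives")
})

test_that("f1 covers the textbook confusion cells", {
  expect_equal(f1Score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  # TP=1 FP=1 FN=1 -> 0.5
  expect_equal(f1Score(c(1, 1, 0), c(0.9, 0.1, 0.9)), 0.5)
  expect_equal(f1Score(c(1, 0), c(0.1, 0.2)), 0)
})

test_that("training on a separable set learns and keeps honest books", {
  set.seed(33)
  ds <- separableSet(40, 40)
  corp <- buildCorpus(sequences(ds), k = 3, s = 1, combined = FALSE)
  emb <- trainCBOW(corp, d = 16, window = 3, epochs = 3, seed = 1)
  ids <- tfcrnn:::.tokenIdMatrix(corp, emb)
  y <- labels(ds)
  idx <- sample(length(y))
  tr <- idx[1:56]; va <- idx[57:68]; te <- idx[69:80]
  cfg <- modelConfig(nConv = 2, convChannels = 8, lstmUnits = 8,
                     fcHidden = 16, seed = 1)
  mdl <- buildModel(cfg, inputLen = ncol(ids), inputDim = 16)
  tc <- trainConfig(epochs = 12, batchSize = 16, seed = 1)
  fit <- fitModel(mdl, ids[tr, ], y[tr], ids[va, ], y[va], tc,
                  embedding = emb)
  h <- modelHistory(fit)
  expect_equal(nrow(h), 12L)
  # loss decreases over the first epochs
  expect_lt(h$loss[4], h$loss[1])
  expect_equal(max(h$valAUC), 1.0)
  # returned model is the best-validation epoch
  expect_equal(h$valAUC[fit@bestEpoch], max(h$valAUC))
  p <- predictProb(fit, tfcrnn:::.idsToArrayFetch(ids[te, ], emb))
  expect_equal(rocAUC(y[te], p), 1.0)
})

test_that("epochs = 1 returns the first-epoch model and history has one row", {
  set.seed(34)
  ds <- separableSet(10, 24)
  corp <- buildCorpus(sequences(ds), k = 3, s = 1, combined = FALSE)
  emb <- oneHotModel(3)
  ids <- tfcrnn:::.tokenIdMatrix(corp, emb)
  y <- labels(ds)
  mdl <- buildModel(modelConfig(nConv = 1, convChannels = 4, lstmUnits = 2,
                                fcHidden = 4, seed = 1),
                    ncol(ids), 64)
  tr <- c(1:7, 11:17); va <- c(8:10, 18:20)
  fit <- fitModel(mdl, ids[tr, ], y[tr], ids[va, ], y[va],
                  trainConfig(epochs = 1, batchSize = 8, seed = 1),
                  embedding = emb)
  expect_equal(nrow(modelHistory(fit)), 1L)
  expect_equal(fit@bestEpoch, 1L)
})

test_that("single-class validation sets are refused", {
  ds <- separableSet(6, 24)
  corp <- buildCorpus(sequences(ds), k = 3, s = 1, combined = FALSE)
  emb <- oneHotModel(3)
  ids <- tfcrnn:::.tokenIdMatrix(corp, emb)
  mdl <- buildModel(modelConfig(nConv = 1, convChannels = 4, lstmUnits = 2,
                                fcHidden = 4), ncol(ids), 64)
  expect_error(
    fitModel(mdl, ids[1:8, ], labels(ds)[1:8], ids[1:3, ], c(1L, 1L, 1L),
             trainConfig(epochs = 1), embedding = emb),
    "single class")
})

test_that("training is bit-reproducible under one seed and adadelta runs", {
  set.seed(35)
  ds <- separableSet(12, 24)
  corp <- buildCorpus(sequences(ds), k = 3, s = 1, combined = FALSE)
  emb <- trainCBOW(corp, d = 8, window = 2, epochs = 2, seed = 2)
  ids <- tfcrnn:::.tokenIdMatrix(corp, emb)
  y <- labels(ds)
  mk <- function(opt) {
    mdl <- buildModel(modelConfig(nConv = 1, convChannels = 4,
                                  lstmUnits = 2, fcHidden = 4, seed = 3),
                      ncol(ids), 8)
    fitModel(mdl, ids[c(1:8, 13:20), ], y[c(1:8, 13:20)],
             ids[c(9:12, 21:24), ], y[c(9:12, 21:24)],
             trainConfig(epochs = 2, batchSize = 8, optimizer = opt,
                         seed = 3), embedding = emb)
  }
  f1 <- mk("adam"); f2 <- mk("adam")
  expect_identical(f1@params, f2@params)
  expect_identical(modelHistory(f1), modelHistory(f2))
  f3 <- mk("adadelta")
  expect_equal(nrow(modelHistory(f3)), 2L)
  expect_false(identical(f1@params, f3@params))
})

test_that("cross-validation runs one fit per fold and averages honestly", {
  set.seed(36)
  ds <- separableSet(24, 30)
  cv <- crossValidate(ds, modelCfg = modelConfig(nConv = 1,
                                                 convChannels = 4,
                                                 lstmUnits = 4,
                                                 fcHidden = 8),
                      trainCfg = trainConfig(epochs = 4, batchSize = 16,
                                             seed = 4),
                      k = 3, s = 1, combined = FALSE, featurizer = "cbow",
                      embedDim = 8, embedEpochs = 2)
  expect_length(cv$perFold, 3L)
  expect_length(cv$models, 3L)
  tab <- metricsTable(cv$perFold)
  expect_equal(cv$mean@rocAUC, mean(tab$rocAUC))
  expect_equal(cv$mean@f1, mean(tab$f1))
  # determinism end to end
  cv2 <- crossValidate(ds, modelCfg = modelConfig(nConv = 1,
                                                  convChannels = 4,
                                                  lstmUnits = 4,
                                                  fcHidden = 8),
                       trainCfg = trainConfig(epochs = 4, batchSize = 16,
                                              seed = 4),
                       k = 3, s = 1, combined = FALSE, featurizer = "cbow",
                       embedDim = 8, embedEpochs = 2)
  expect_equal(metricsTable(cv2$perFold), tab)
})

test_that("ablation grid emits one row per cell and survives infeasible cells", {
  set.seed(37)
  ds <- separableSet(18, 24)
  grid <- expand.grid(k = c(3, 30), featurizer = c("cbow", "onehot"),
                      stringsAsFactors = FALSE)
  tab <- runAblation(ds, grid,
                     modelCfg = modelConfig(nConv = 1, convChannels = 4,
                                            lstmUnits = 2, fcHidden = 4),
                     trainCfg = trainConfig(epochs = 2, batchSize = 16,
                                            seed = 5),
                     embedDim = 8, embedEpochs = 1)
  expect_equal(nrow(tab), 4L)
  # k = 30 > 24 bp sequences is infeasible (raw-mode length is 24... but
  # combined is the default input mode: 96 bp, so k = 30 still tokenizes;
  # onehot at k = 30 is the infeasible featurizer: 4^30 columns)
  expect_true(all(tab$status %in% c("ok", "failed")))
  expect_true(any(tab$status == "failed"))
  ok <- tab[tab$status == "ok", ]
  expect_true(all(is.finite(ok$rocAUC)))
  out <- withr::local_tempfile(fileext = ".tsv")
  runAblation(ds, data.frame(k = 3),
              modelCfg = modelConfig(nConv = 1, convChannels = 4,
                                     lstmUnits = 2, fcHidden = 4),
              trainCfg = trainConfig(epochs = 1, batchSize = 16, seed = 5),
              embedDim = 4, embedEpochs = 1, outFile = out)
  expect_true(file.exists(out))
  expect_equal(nrow(read.table(out, header = TRUE, sep = "\t")), 1L)
})
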