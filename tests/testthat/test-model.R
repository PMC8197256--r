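test_that("bi-LSTM step with zero parameters gives the closed form", {
  H <- 3; d <- 4
  p <- zeroLstmParams(H, d)
  cPrev <- c(1, -2, 0.5)
  st <- biLstmStep(rnorm(d), numeric(H), cPrev, p)
  # gates sigmoid(0) = 0.5, candidate tanh(0) = 0
  expect_equal(st$c, 0.5 * cPrev)
  expect_equal(st$h, 0.5 * tanh(0.5 * cPrev))
})

test_that("bi-LSTM step matches the scalar-loop oracle on random instances", {
  set.seed(20)
  for (i in 1:100) {
    H <- sample(1:4, 1); d <- sample(1:5, 1)
    p <- randomLstmParams(H, d)
    x <- rnorm(d); h0 <- rnorm(H, sd = 0.3); c0 <- rnorm(H)
    got <- biLstmStep(x, h0, c0, p)
    want <- scalarLstmStep(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-6)
    expect_equal(got$c, want$c, tolerance = 1e-6)
    expect_true(all(abs(got$h) < 1))   # o in (0,1), tanh in (-1,1)
  }
})

test_that("bi-LSTM step validates shapes", {
  p <- randomLstmParams(2, 3)
  expect_error(biLstmStep(rnorm(4), numeric(2), numeric(2), p), "shape")
  expect_error(biLstmStep(rnorm(3), numeric(3), numeric(3), p), "shape")
})

test_that("compiled LSTM sequence agrees with iterated R steps", {
  set.seed(21)
  H <- 3; d <- 4; L <- 7
  p <- randomLstmParams(H, d)
  X <- matrix(rnorm(L * d), L, d)
  W <- rbind(p$Wf, p$Wi, p$Wc, p$Wo)
  U <- rbind(p$Uf, p$Ui, p$Uc, p$Uo)
  b <- c(p$bf, p$bi, p$bc, p$bo)
  for (rev in c(FALSE, TRUE)) {
    got <- tfcrnn:::lstm_seq_cpp(X, W, U, b, rev)
    h <- numeric(H); cc <- numeric(H)
    ord <- if (rev) L:1 else 1:L
    for (t in ord) {
      st <- biLstmStep(X[t, ], h, cc, p)
      h <- st$h; cc <- st$c
      expect_equal(got[t, ], h, tolerance = 1e-10)
    }
  }
})

test_that("model builds with the documented shapes and length bookkeeping", {
  cfg <- modelConfig(seed = 3)
  mdl <- buildModel(cfg, inputLen = 798, inputDim = 100)
  expect_equal(dim(mdl@params$conv1_W), c(16L, 300L))
  expect_equal(dim(mdl@params$lstm_fw_W), c(64L, 16L))
  expect_equal(dim(mdl@params$fc1_W), c(32L, 32L))     # maxpool head: 2H
  flat <- buildModel(modelConfig(rnnHead = "flatten", seed = 3), 798, 100)
  expect_equal(dim(flat@params$fc1_W), c(32L, 2L * 16L * 99L))
  # 798 -> 399 -> 199 -> 99 under three floor-halving pools
  expect_equal(tfcrnn:::.pooledLength(798L, cfg), 99L)
  expect_equal(tfcrnn:::.pooledLength(200L, cfg), 25L)
  expect_true(all(vapply(mdl@params[grepl("_b$|beta", names(mdl@params))],
                         function(b) all(b == 0), logical(1))))
})

test_that("too-short inputs are rejected with the computed minimum", {
  expect_error(buildModel(modelConfig(), inputLen = 7, inputDim = 10),
               "minimum 8")
})

test_that("parameter count is seed-invariant but values are not", {
  m1 <- buildModel(modelConfig(seed = 1), 64, 10)
  m2 <- buildModel(modelConfig(seed = 2), 64, 10)
  expect_equal(nParams(m1), nParams(m2))
  expect_false(identical(m1@params$conv1_W, m2@params$conv1_W))
  m1b <- buildModel(modelConfig(seed = 1), 64, 10)
  expect_identical(m1@params, m1b@params)
})

test_that("ablation variants drop the expected modules", {
  cnn <- buildModel(modelConfig(arch = "cnn_only"), 64, 10)
  expect_false(any(grepl("lstm", names(cnn@params))))
  rnn <- buildModel(modelConfig(arch = "rnn_only"), 64, 10)
  expect_false(any(grepl("conv", names(rnn@params))))
  expect_true(all(c("lstm_fw_W", "lstm_bw_W") %in% names(rnn@params)))
})

test_that("forward pass emits calibrated probabilities deterministically", {
  set.seed(22)
  cfg <- modelConfig(seed = 5)
  mdl <- buildModel(cfg, inputLen = 64, inputDim = 10)
  X <- array(rnorm(64 * 10 * 8), dim = c(64, 10, 8))
  p1 <- predictProb(mdl, X)
  expect_length(p1, 8L)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predictProb(mdl, X))
  # zeroed final layer -> sigmoid(0) = 0.5 exactly
  mdl0 <- mdl
  mdl0@params$fc2_W[] <- 0
  mdl0@params$fc2_b[] <- 0
  expect_equal(predictProb(mdl0, X), rep(0.5, 8))
  # increasing the output bias strictly increases every probability
  mdlUp <- mdl
  mdlUp@params$fc2_b[] <- mdl@params$fc2_b + 1
  expect_true(all(predictProb(mdlUp, X) > p1))
  expect_error(predictProb(mdl, array(0, c(10, 10, 2))), "expects")
})

test_that("analytic gradients match finite differences on all variants", {
  set.seed(23)
  for (case in list(list(arch = "hybrid", bn = TRUE, head = "maxpool"),
                    list(arch = "hybrid", bn = FALSE, head = "flatten"),
                    list(arch = "cnn_only", bn = TRUE, head = "maxpool"),
                    list(arch = "rnn_only", bn = FALSE, head = "maxpool"),
                    list(arch = "rnn_only", bn = FALSE, head = "flatten"))) {
    cfg <- modelConfig(nConv = 2, convChannels = 3, kernelSize = 3,
                       poolWindow = 2, lstmUnits = 2, fcHidden = 4,
                       dropout = 0, batchNorm = case$bn, arch = case$arch,
                       rnnHead = case$head, seed = 7)
    mdl <- buildModel(cfg, inputLen = 12, inputDim = 5)
    n <- 3
    X <- array(rnorm(12 * 5 * n), dim = c(12, 5, n))
    y <- c(1, 0, 1)
    cfgl <- tfcrnn:::.cfgList(cfg)
    mask <- matrix(1, 4, n)
    res <- tfcrnn:::nn_fwbw(X, y, mdl@params, cfgl, mask)
    for (nm in names(mdl@params)) {
      idx <- sample(length(mdl@params[[nm]]), 1)
      eps <- 1e-6
      p1 <- mdl@params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
      p2 <- mdl@params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
      ng <- (tfcrnn:::nn_fwbw(X, y, p1, cfgl, mask)$loss -
             tfcrnn:::nn_fwbw(X, y, p2, cfgl, mask)$loss) / (2 * eps)
      expect_equal(res$grads[[nm]][idx], ng, tolerance = 1e-4,
                   label = sprintf("%s gradient (%s)", nm, case$arch))
    }
  }
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  mdl <- buildModel(modelConfig(seed = 1), 64, 10)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(mdl, path)
  back <- loadModel(path, config = modelConfig(seed = 1))
  expect_identical(back@params, mdl@params)
  expect_error(loadModel(path, config = modelConfig(lstmUnits = 8L)),
               "does not match")
})
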