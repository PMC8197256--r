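test_that("GC content excludes N and rejects all-N input", {
  expect_equal(gcContent(c("GGCC", "ATAT", "ACGT")), c(1, 0, 0.5))
  expect_equal(gcContent("ACGN"), 2 / 3)
  expect_error(gcContent("NNN"), "all-N")
})

test_that("positives are extracted from the top-scoring peaks, resized", {
  set.seed(10)
  genome <- DNAStringSet(c(chr1 = randomDNA(10000), chr2 = randomDNA(5000)))
  starts <- seq(300, 8000, length.out = 20)
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = starts, width = 400))
  peaks$signalValue <- seq_len(20)   # peak 20 scores highest
  pos <- extractPositives(peaks, genome, topN = 5, width = 200)
  expect_length(pos, 5L)
  expect_equal(unique(width(pos)), 200L)
  # best peak's window is centred on its midpoint
  mid <- (GenomicRanges::start(peaks)[20] + GenomicRanges::end(peaks)[20]) %/% 2
  expect_equal(as.character(pos[[1]]),
               as.character(subseq(genome[["chr1"]], mid - 100, mid + 99)))
})

test_that("summit column recentres the window (hand-checked toy record)", {
  genome <- DNAStringSet(c(chr1 = paste(rep("ACGT", 500), collapse = "")))
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start = 901, end = 1300))
  pk$signalValue <- 5
  pk$peak <- 40L     # summit at 901 + 40 = 941
  pos <- extractPositives(pk, genome, topN = 1, width = 200)
  expect_equal(as.character(pos[[1]]),
               as.character(subseq(genome[["chr1"]], 841, 1040)))
})

test_that("bound handling: clamped topN warns, out-of-bounds skipped, missing chrom errors", {
  genome <- DNAStringSet(c(chr1 = randomDNA(1000)))
  pk <- GenomicRanges::GRanges(c("chr1", "chr1"),
                               IRanges::IRanges(start = c(400, 30), width = 100))
  pk$signalValue <- c(2, 1)
  expect_warning(
    expect_warning(pos <- extractPositives(pk, genome, topN = 5, width = 200),
                   "exceeds peak count"),
    "outside chromosome bounds")
  # second peak's window would start below 1 -> skipped with warning
  expect_warning(pos <- extractPositives(pk, genome, topN = 2, width = 200),
                 "outside chromosome bounds")
  expect_length(suppressWarnings(
    extractPositives(pk, genome, topN = 2, width = 200)), 1L)
  pk2 <- GenomicRanges::GRanges("chrX", IRanges::IRanges(500, 600))
  pk2$signalValue <- 1
  expect_error(extractPositives(pk2, genome, topN = 1), "absent")
})

test_that("narrowPeak files round through the reader", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(paste(c("chr1\t100\t500\tpeak1\t0\t.\t13.5\t-1\t-1\t250",
                     "chr1\t900\t1300\tpeak2\t0\t.\t22.0\t-1\t-1\t40"),
                   collapse = "\n"), path)
  gr <- readPeaks(path)
  expect_length(gr, 2L)
  expect_equal(gr$signalValue, c(13.5, 22.0))
  expect_equal(gr$peak, c(250L, 40L))
  expect_equal(GenomicRanges::start(gr), c(101L, 901L))  # 1-based in R
})

test_that("matched negatives honour ratio, length, GC tolerance and partners", {
  set.seed(11)
  pos <- DNAStringSet(setNames(
    vapply(1:100, function(i) randomDNA(200), character(1)),
    sprintf("p%d", 1:100)))
  neg <- generateMatchedNegatives(pos, ratio = 2, sampler = "shuffle",
                                  seed = 1)
  expect_length(neg, 200L)
  expect_equal(unique(width(neg)), 200L)
  partner <- metadata(neg)$partner
  expect_equal(tabulate(partner, 100), rep(2L, 100))
  # shuffle preserves composition exactly
  expect_equal(gcContent(neg), gcContent(pos)[partner])
  expect_false(any(as.character(neg) %in% as.character(pos)))
})

test_that("iid sampler matches mean GC closely (Monte-Carlo)", {
  set.seed(12)
  pos <- sampleBackground(300, 200, gc = 0.45)
  names(pos) <- sprintf("p%d", seq_along(pos))
  neg <- generateMatchedNegatives(pos, ratio = 1, sampler = "iid",
                                  gcTolerance = 0.02, seed = 2)
  expect_length(neg, 300L)
  expect_lt(abs(mean(gcContent(neg)) - mean(gcContent(pos))), 0.01)
  expect_true(all(abs(gcContent(neg) - gcContent(pos)) <= 0.02 + 1e-12))
})

test_that("pool sampler draws windows within tolerance", {
  set.seed(13)
  pos <- sampleBackground(20, 50, gc = 0.5)
  names(pos) <- sprintf("p%d", seq_along(pos))
  pool <- sampleBackground(5, 2000, gc = 0.5)
  neg <- generateMatchedNegatives(pos, ratio = 1, sampler = "pool",
                                  pool = pool, gcTolerance = 0.05, seed = 3)
  expect_length(neg, 20L)
  expect_true(all(abs(gcContent(neg) - gcContent(pos)) <= 0.05 + 1e-12))
  expect_error(generateMatchedNegatives(pos, sampler = "pool"),
               "background pool")
})

test_that("fold splits partition, stratify and reproduce under a seed", {
  lab <- rep(c(1L, 0L), c(100, 200))
  fs <- splitFolds(lab, nFolds = 3, seed = 5)
  expect_equal(sort(unique(fs@fold)), 1:3)
  expect_equal(tabulate(fs@fold, 3), rep(100L, 3))
  # union of folds = dataset, pairwise disjoint: each index has one fold
  expect_length(fs@fold, 300L)
  for (f in 1:3) {
    perFold <- table(lab[fs@fold == f])
    expect_true(all(abs(perFold - c(200, 100) / 3) <= 1))
    # validation drawn only from training folds, floor(1/8 * 200) = 25
    expect_equal(sum(fs@valMask[[f]]), 25L)
    expect_false(any(fs@valMask[[f]] & fs@fold == f))
  }
  fs2 <- splitFolds(lab, nFolds = 3, seed = 5)
  expect_identical(fs@fold, fs2@fold)
  expect_identical(fs@valMask, fs2@valMask)
  expect_error(splitFolds(c(1L, 0L), nFolds = 3), "fewer records")
})

test_that("240 training records at 1/8 yield 30 validation records", {
  lab <- rep(c(1L, 0L), 180)
  fs <- splitFolds(lab, nFolds = 3, seed = 1)
  expect_equal(sum(fs@valMask[[1]]), 30L)   # 240 train -> 30 val
})

test_that("dataset FASTA + manifest round-trips", {
  set.seed(14)
  ds <- separableSet(10, 30)
  fs <- splitFolds(ds, seed = 2)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir, prefix = "toy", folds = fs)
  back <- readDataset(dir, prefix = "toy")
  expect_equal(as.character(sequences(back)), as.character(sequences(ds)))
  expect_equal(labels(back), labels(ds))
  man <- back@meta$manifest
  expect_equal(man$fold, fs@fold)
})
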