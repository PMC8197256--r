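#' GC content of sequences
#'
#' Fraction (G + C) / (non-N length); N bases are excluded from both
#' numerator and denominator. All-N sequences have no defined GC
#' content and raise an error.
#'
#' @param x sequences (character or `DNAStringSet`).
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' gcContent(c("GGCC", "ATAT", "ACGT"))  # 1, 0, 0.5
#' @export
gcContent <- function(x) {
  dna <- asDNA(x)
  freq <- letterFrequency(dna, letters = c("G", "C", "N"))
  denom <- width(dna) - freq[, "N"]
  if (any(denom == 0))
    stop("GC content undefined for all-N sequence (index ",
         which(denom == 0)[1], ")")
  unname((freq[, "G"] + freq[, "C"]) / denom)
}

#' Read a narrowPeak / BED peak file
#'
#' Tab-separated, 0-based half-open coordinates. Columns beyond the
#' first six follow the ENCODE narrowPeak convention (signalValue,
#' pValue, qValue, peak). Uses `rtracklayer::import` when available,
#' falling back to a minimal reader.
#'
#' @param path file path.
#' @return a [GenomicRanges::GRanges] with `signalValue` (and `peak`
#'   summit offset when present) in `mcols`.
#' @export
readPeaks <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    ncols <- length(strsplit(readLines(path, n = 1L), "\t")[[1]])
    gr <- if (ncols >= 10L)
      rtracklayer::import(path, format = "BED", extraCols = extra)
    else rtracklayer::import(path, format = "BED")
    if (is.null(gr$signalValue))
      gr$signalValue <- if (!is.null(gr$score)) as.numeric(gr$score) else 0
    return(gr)
  }
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]))
  gr$signalValue <- if (ncol(tab) >= 7L) tab[[7]] else
    if (ncol(tab) >= 5L) tab[[5]] else 0
  if (ncol(tab) >= 10L) gr$peak <- tab[[10]]
  gr
}

#' Extract fixed-width positive sequences from ranked peaks
#'
#' Selects the `topN` highest-scoring peaks (narrowPeak `signalValue`;
#' ties broken by coordinate for determinism) and extracts a fixed-width
#' window centered on the peak summit when a `peak` offset column is
#' present (and non-negative), otherwise on the interval midpoint.
#' Windows falling outside chromosome bounds are skipped with a warning.
#'
#' @param peaks a `GRanges` (e.g. from [readPeaks()]) or peak file path.
#' @param genome named [Biostrings::DNAStringSet] or FASTA path.
#' @param topN number of peaks to keep; clamped to the peak count with
#'   a warning when larger.
#' @param width window width in bp (default 200).
#' @return a [Biostrings::DNAStringSet] of uppercase `width`-bp
#'   sequences named `pos_<rank>`.
#' @export
extractPositives <- function(peaks, genome, topN, width = 200L) {
  if (is.character(peaks)) peaks <- readPeaks(peaks)
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  score <- if (!is.null(peaks$signalValue)) peaks$signalValue
           else as.numeric(peaks$score)
  if (is.null(score)) stop("peaks carry neither signalValue nor score")
  ord <- order(-score, as.factor(seqnames(peaks)), start(peaks))
  if (topN > length(peaks)) {
    warning(sprintf("topN = %d exceeds peak count %d; returning all peaks",
                    topN, length(peaks)))
    topN <- length(peaks)
  }
  sel <- peaks[ord[seq_len(topN)]]
  chrs <- as.character(seqnames(sel))
  missing <- setdiff(unique(chrs), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  center <- if (!is.null(sel$peak) && all(!is.na(sel$peak)) && all(sel$peak >= 0))
    start(sel) + sel$peak
  else (start(sel) + end(sel)) %/% 2L
  half <- width %/% 2L
  from <- center - half
  to <- from + width - 1L
  ok <- from >= 1L & to <= width(genome)[match(chrs, names(genome))]
  if (any(!ok))
    warning(sum(!ok), " window(s) outside chromosome bounds were skipped")
  out <- DNAStringSet(vapply(which(ok), function(i) {
    toupper(as.character(subseq(genome[[chrs[i]]], from[i], to[i])))
  }, character(1)))
  names(out) <- sprintf("pos_%d", which(ok))
  out
}

.sampleIID <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate GC- and length-matched negatives
#'
#' For each positive, emits `ratio` negative sequences of the same
#' length whose per-sequence GC content is within `gcTolerance` of its
#' partner positive. Three samplers are available:
#' \describe{
#'   \item{shuffle}{mononucleotide shuffle of the partner positive:
#'     exact GC and length match, repeat/motif structure destroyed
#'     (default).}
#'   \item{iid}{i.i.d. bases drawn at the partner's GC fraction,
#'     rejection-sampled to within `gcTolerance`.}
#'   \item{pool}{random windows from a user-supplied background
#'     `DNAStringSet`, rejection-sampled to within `gcTolerance`;
#'     the only mode that approximates repeat-fraction matching.}
#' }
#' When `maxAttempts` draws cannot satisfy the tolerance it is doubled
#' with a warning; a second failure is an error. Negatives identical to
#' any positive are rejected and resampled.
#'
#' @param positives [Biostrings::DNAStringSet] of equal-width positives.
#' @param ratio negatives per positive (1, 2 or 3 in the study design).
#' @param sampler one of "shuffle", "iid", "pool".
#' @param gcTolerance per-sequence GC tolerance (default 0.02).
#' @param pool background `DNAStringSet` for the "pool" sampler.
#' @param maxAttempts rejection-sampling budget per negative.
#' @param seed optional RNG seed.
#' @return [Biostrings::DNAStringSet] of `ratio * length(positives)`
#'   negatives named `neg_<i>`, with `metadata(.)$partner` giving each
#'   negative's positive partner index.
#' @export
generateMatchedNegatives <- function(positives, ratio = 1L,
                                     sampler = c("shuffle", "iid", "pool"),
                                     gcTolerance = 0.02, pool = NULL,
                                     maxAttempts = 1000L, seed = NULL) {
  sampler <- match.arg(sampler)
  pos <- asDNA(positives)
  if (length(pos) == 0L) stop("positives must be non-empty")
  if (length(unique(width(pos))) != 1L)
    stop("positives must share one length")
  if (!ratio %in% 1:3)
    warning("ratio ", ratio, " is outside the study design {1, 2, 3}")
  if (!is.null(seed)) set.seed(seed)
  if (sampler == "pool") {
    if (is.null(pool)) stop("sampler = 'pool' requires a background pool")
    pool <- asDNA(pool)
    if (any(width(pool) < width(pos)[1]))
      stop("all pool sequences must be at least as wide as the positives")
  }
  len <- width(pos)[1]
  posChr <- as.character(pos)
  posSet <- new.env(hash = TRUE)
  for (p in posChr) assign(p, TRUE, envir = posSet)
  posGC <- gcContent(pos)
  posLetters <- strsplit(posChr, "")

  drawOne <- function(i, tol) {
    for (att in seq_len(maxAttempts)) {
      cand <- switch(sampler,
        shuffle = paste(sample(posLetters[[i]]), collapse = ""),
        iid = .sampleIID(len, posGC[i]),
        pool = {
          j <- sample.int(length(pool), 1L)
          st <- sample.int(width(pool)[j] - len + 1L, 1L)
          as.character(subseq(pool[[j]], st, st + len - 1L))
        })
      if (exists(cand, envir = posSet, inherits = FALSE)) next
      g <- tryCatch(gcContent(cand), error = function(e) NA_real_)
      if (!is.na(g) && abs(g - posGC[i]) <= tol) return(cand)
    }
    NULL
  }

  partner <- rep(seq_along(pos), each = ratio)
  out <- character(length(partner))
  for (j in seq_along(partner)) {
    cand <- drawOne(partner[j], gcTolerance)
    if (is.null(cand)) {
      warning(sprintf(
        "could not match GC within %.3f after %d attempts; relaxing to %.3f",
        gcTolerance, maxAttempts, 2 * gcTolerance))
      cand <- drawOne(partner[j], 2 * gcTolerance)
      if (is.null(cand))
        stop("negative sampling failed even at relaxed tolerance")
    }
    out[j] <- cand
  }
  neg <- DNAStringSet(out)
  names(neg) <- sprintf("neg_%d", seq_along(neg))
  metadata(neg)$partner <- partner
  neg
}

#' Assemble a labeled dataset
#'
#' @param positives,negatives equal-width `DNAStringSet`s.
#' @param meta optional provenance list.
#' @return a [LabeledSeqSet-class] (positives first).
#' @export
labeledSeqSet <- function(positives, negatives, meta = list()) {
  pos <- asDNA(positives); neg <- asDNA(negatives)
  if (is.null(names(pos))) names(pos) <- sprintf("pos_%d", seq_along(pos))
  if (is.null(names(neg))) names(neg) <- sprintf("neg_%d", seq_along(neg))
  seqs <- c(pos, neg)
  new("LabeledSeqSet", sequences = seqs,
      labels = c(rep(1L, length(pos)), rep(0L, length(neg))),
      ratio = length(neg) / length(pos), meta = meta)
}

#' Stratified cross-validation folds with an inner validation split
#'
#' Partitions records into `nFolds` folds, stratified by label so every
#' fold preserves the class ratio to within one record. For each
#' held-out fold, `floor(valFrac * nTrain)` of the remaining (training)
#' records are flagged as the validation set used for model selection;
#' the default `valFrac = 1/8` mirrors the study protocol of three-fold
#' cross-validation with 1/8 of training samples for validation.
#'
#' @param x a [LabeledSeqSet-class] or a 0/1 label vector.
#' @param nFolds number of folds (default 3).
#' @param valFrac validation fraction of the training portion.
#' @param seed RNG seed; same seed, same split.
#' @return a [FoldSplit-class].
#' @export
splitFolds <- function(x, nFolds = 3L, valFrac = 1 / 8, seed = 1L) {
  lab <- if (is(x, "LabeledSeqSet")) x@labels else as.integer(x)
  nFolds <- as.integer(nFolds)
  n <- length(lab)
  if (n < nFolds) stop("fewer records (", n, ") than folds (", nFolds, ")")
  set.seed(seed)
  fold <- integer(n)
  off <- 0L   # rotate the round-robin start between classes so that
              # fold sizes stay exactly balanced overall
  for (cl in unique(lab)) {
    idx <- sample(which(lab == cl))
    fold[idx] <- (off + seq_along(idx) - 1L) %% nFolds + 1L
    off <- (off + length(idx)) %% nFolds
  }
  valMask <- lapply(seq_len(nFolds), function(f) {
    train <- which(fold != f)
    nval <- floor(valFrac * length(train))
    m <- logical(n)
    m[sample(train, nval)] <- TRUE
    m
  })
  new("FoldSplit", fold = fold, valMask = valMask,
      nFolds = as.integer(nFolds), seed = as.integer(seed))
}

#' Write/read a labeled dataset as FASTA + manifest
#'
#' Positives and negatives are written as `<prefix>_pos.fa` and
#' `<prefix>_neg.fa`; a TSV manifest (`<prefix>_manifest.tsv`) records
#' id, label and, when a [FoldSplit-class] is given, fold and
#' validation flags (one column per held-out fold).
#'
#' @param ds a [LabeledSeqSet-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param folds optional [FoldSplit-class].
#' @return invisibly, the manifest path. `readDataset` returns a
#'   [LabeledSeqSet-class].
#' @export
writeDataset <- function(ds, dir, prefix = "dataset", folds = NULL) {
  stopifnot(is(ds, "LabeledSeqSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- ds@sequences[ds@labels == 1L]
  neg <- ds@sequences[ds@labels == 0L]
  writeXStringSet(pos, file.path(dir, paste0(prefix, "_pos.fa")))
  writeXStringSet(neg, file.path(dir, paste0(prefix, "_neg.fa")))
  man <- data.frame(id = names(ds@sequences), label = ds@labels)
  if (!is.null(folds)) {
    man$fold <- folds@fold
    for (f in seq_len(folds@nFolds))
      man[[paste0("val_fold", f)]] <- as.integer(folds@valMask[[f]])
  }
  mpath <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  write.table(man, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir, prefix = "dataset") {
  pos <- readDNAStringSet(file.path(dir, paste0(prefix, "_pos.fa")))
  neg <- readDNAStringSet(file.path(dir, paste0(prefix, "_neg.fa")))
  man <- read.table(file.path(dir, paste0(prefix, "_manifest.tsv")),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ds <- labeledSeqSet(pos, neg, meta = list(manifest = man))
  ds
}
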