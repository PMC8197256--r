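.corpusSentences <- function(corpus) {
  if (is(corpus, "KmerCorpus")) return(corpus@sentences)
  if (is.list(corpus) && all(vapply(corpus, is.character, logical(1))))
    return(corpus)
  stop("corpus must be a KmerCorpus or a list of token character vectors")
}

#' Train a CBOW k-mer embedding
#'
#' Trains a continuous bag-of-words word2vec model with negative
#' sampling on a k-mer corpus, treating each sequence's token list as a
#' sentence. Every token occurring at least `minCount` times receives a
#' `d`-dimensional real vector; training is single-threaded and fully
#' deterministic for a fixed `seed`.
#'
#' @param corpus a [KmerCorpus-class] (or list of token vectors).
#' @param d embedding dimension (default 100).
#' @param window context half-width in tokens (default 5).
#' @param epochs passes over the corpus (default 10).
#' @param negative negative samples per target (default 5).
#' @param minCount minimum token frequency for the vocabulary (default 1).
#' @param alpha initial learning rate, linearly decayed (default 0.05).
#' @param seed integer RNG seed (default 1).
#' @return an [EmbeddingModel-class].
#' @export
trainCBOW <- function(corpus, d = 100L, window = 5L, epochs = 10L,
                      negative = 5L, minCount = 1L, alpha = 0.05,
                      seed = 1L) {
  sent <- .corpusSentences(corpus)
  if (length(sent) == 0L) stop("corpus is empty")
  d <- as.integer(d)
  if (d < 1L) stop("embedding dimension must be >= 1")
  counts <- table(unlist(sent, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= minCount])
  if (length(vocab) == 0L) stop("no token reaches minCount")
  ids <- lapply(sent, function(tk) {
    m <- match(tk, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  if (sum(pmax(lengths(ids) - 1L, 0L)) == 0L)
    warning("corpus provides no context pairs (sentences shorter than 2 ",
            "tokens); returning a degenerate model with initial vectors")
  vec <- cbow_train_cpp(ids, length(vocab), d, as.integer(window),
                        as.integer(epochs), as.integer(negative),
                        alpha, as.integer(seed),
                        as.numeric(counts[vocab]))
  rownames(vec) <- vocab
  k <- if (is(corpus, "KmerCorpus")) corpus@k else nchar(vocab[1])
  s <- if (is(corpus, "KmerCorpus")) corpus@s else 1L
  new("EmbeddingModel", vectors = vec, k = as.integer(k), s = as.integer(s),
      meta = list(featurizer = "cbow", window = as.integer(window),
                  epochs = as.integer(epochs), negative = as.integer(negative),
                  minCount = as.integer(minCount), alpha = alpha,
                  seed = as.integer(seed)))
}

#' One-hot k-mer "embedding"
#'
#' The baseline featurizer: the identity matrix over the 4^k
#' lexicographically ordered A/C/G/T k-mers, wrapped as an
#' [EmbeddingModel-class] so it is interchangeable with a CBOW model.
#' Tokens containing N have no column and are rejected (strict) or
#' mapped to the zero row (OOV policy) downstream.
#'
#' @param k k-mer length.
#' @param s stride recorded as provenance.
#' @return an [EmbeddingModel-class] with `featurizer = "onehot"`.
#' @export
oneHotModel <- function(k = 3L, s = 1L) {
  k <- as.integer(k)
  if (k > 10L)
    stop("one-hot vocabulary of size 4^", k, " is infeasible; use the CBOW featurizer for large k")
  vocab <- sort(apply(do.call(expand.grid,
                              rep(list(c("A", "C", "G", "T")), k)),
                      1, function(r) paste(rev(r), collapse = "")))
  vec <- diag(length(vocab))
  rownames(vec) <- vocab
  new("EmbeddingModel", vectors = vec, k = k, s = as.integer(s),
      meta = list(featurizer = "onehot"))
}

#' Lexicographic k-mer index
#'
#' 1-based index of an A/C/G/T k-mer in lexicographic order
#' ("AAA" -> 1, "AAC" -> 2, ..., "TTT" -> 4^k).
#'
#' @param tokens character vector of k-mers.
#' @return integer vector; NA for tokens containing N.
#' @export
kmerIndex <- function(tokens) {
  k <- unique(nchar(tokens))
  if (length(k) != 1L) stop("tokens must share one length")
  codes <- matrix(match(unlist(strsplit(tokens, "")),
                        c("A", "C", "G", "T")) - 1L,
                  nrow = k)
  idx <- as.integer(colSums(codes * 4^((k - 1):0)) + 1L)
  idx
}

#' Embed a sentence or corpus as a dense matrix
#'
#' Row i of the result is the embedding vector of token i; a 798-token
#' sentence embedded at d = 100 yields a 798 x 100 matrix.
#' Out-of-vocabulary tokens map to the zero vector (deterministic and
#' shape-preserving; neutral under downstream convolution).
#'
#' @param x a token character vector or a [KmerCorpus-class].
#' @param model an [EmbeddingModel-class] with matching k.
#' @return a numeric matrix (tokens x d), or a list of such matrices
#'   for a corpus.
#' @export
embedSequence <- function(x, model) {
  stopifnot(is(model, "EmbeddingModel"))
  if (is(x, "KmerCorpus")) {
    if (x@k != model@k)
      stop(sprintf("k mismatch: corpus k = %d, model k = %d", x@k, model@k))
    return(lapply(sentences(x), embedSequence, model = model))
  }
  if (!is.character(x)) stop("x must be a token vector or KmerCorpus")
  if (length(x) && any(nchar(x) != model@k))
    stop(sprintf("k mismatch: tokens of length %d, model k = %d",
                 unique(nchar(x))[1], model@k))
  V <- model@vectors
  idx <- match(x, rownames(V))
  out <- matrix(0, nrow = length(x), ncol = ncol(V))
  hit <- !is.na(idx)
  out[hit, ] <- V[idx[hit], , drop = FALSE]
  out
}

#' One-hot encode a k-mer sentence
#'
#' @param x token character vector or [KmerCorpus-class].
#' @param strict error on tokens containing N (default); otherwise they
#'   become all-zero rows.
#' @return matrix (tokens x 4^k) with exactly one 1 per row (strict).
#' @export
oneHotKmers <- function(x, strict = TRUE) {
  if (is(x, "KmerCorpus"))
    return(lapply(sentences(x), oneHotKmers, strict = strict))
  if (strict && any(grepl("N", x, fixed = TRUE)))
    stop("tokens containing N cannot be one-hot encoded (strict mode): ",
         x[grepl("N", x, fixed = TRUE)][1])
  embedSequence(x, oneHotModel(k = unique(nchar(x))))
}

#' Read/write word vectors in word2vec text format
#'
#' Header line "vocab_size dim", then one line per token:
#' the token followed by its vector components, space-separated.
#'
#' @param model an [EmbeddingModel-class].
#' @param path file path.
#' @param k,s provenance to attach on read (k defaults to the token
#'   length found in the file).
#' @return `readWordVectors` returns an [EmbeddingModel-class].
#' @export
writeWordVectors <- function(model, path) {
  stopifnot(is(model, "EmbeddingModel"))
  V <- model@vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(V), ncol(V)), con)
  writeLines(paste(rownames(V),
                   apply(V, 1, function(r) paste(format(r, digits = 17),
                                                 collapse = " "))),
             con)
  invisible(path)
}

#' @rdname writeWordVectors
#' @export
readWordVectors <- function(path, k = NULL, s = 1L) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " +")
  tokens <- vapply(parts, `[`, character(1), 1L)
  V <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(V) <- tokens
  if (nrow(V) != hdr[1]) stop("vector count does not match header")
  if (is.null(k)) k <- nchar(tokens[1])
  new("EmbeddingModel", vectors = V, k = as.integer(k), s = as.integer(s),
      meta = list(featurizer = "cbow", source = path))
}

# token-id matrix for equal-length sentences; OOV id = nrow(vectors)+1,
# pointing at the appended zero row of .augmentedVectors().
.tokenIdMatrix <- function(corpus, model) {
  sent <- .corpusSentences(corpus)
  n <- lengths(sent)
  if (length(unique(n)) != 1L)
    stop("sentences must share one token count for batched training")
  vocab <- rownames(model@vectors)
  ids <- matrix(match(unlist(sent), vocab), nrow = length(sent),
                ncol = n[1], byrow = TRUE)
  ids[is.na(ids)] <- nrow(model@vectors) + 1L
  ids
}

.augmentedVectors <- function(model) {
  rbind(model@vectors, 0)
}

#' Token-id matrix and embedded batch array
#'
#' `tokenIdMatrix` maps every sentence of an equal-length corpus to a
#' row of vocabulary indices (out-of-vocabulary tokens get the index of
#' an all-zero padding row); `embeddedArray` materializes such an id
#' matrix as the 3-D batch array `(tokens, d, records)` the classifier
#' consumes. Together they form the bridge from a [KmerCorpus-class]
#' to [fitModel()]/[predictProb()] without holding every embedded
#' matrix in memory during training.
#'
#' @param corpus a [KmerCorpus-class] with equal-length sentences.
#' @param model an [EmbeddingModel-class].
#' @param ids an integer matrix from `tokenIdMatrix`.
#' @return `tokenIdMatrix`: integer matrix (records x tokens);
#'   `embeddedArray`: numeric array (tokens x d x records).
#' @export
tokenIdMatrix <- function(corpus, model) .tokenIdMatrix(corpus, model)

#' @rdname tokenIdMatrix
#' @export
embeddedArray <- function(ids, model) .idsToArrayFetch(ids, model)
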