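#' Validate and normalize DNA input
#'
#' Accepts a character vector, [Biostrings::DNAString] or
#' [Biostrings::DNAStringSet]; uppercases and checks that only
#' A, C, G, T, N occur. The error names the first offending position.
#'
#' @param x sequences.
#' @param what label used in error messages.
#' @return a [Biostrings::DNAStringSet].
#' @export
asDNA <- function(x, what = "sequence") {
  if (is(x, "DNAStringSet")) {
    chr <- as.character(x)
  } else if (is(x, "XString")) {
    chr <- as.character(x)
  } else if (is.character(x)) {
    chr <- x
  } else {
    stop("cannot interpret ", what, " of class ", class(x)[1])
  }
  chr <- toupper(chr)
  if (any(nchar(chr) < 1L)) stop(what, " must have length >= 1")
  bad <- regexpr("[^ACGTN]", chr)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' at position %d of %s %d",
                 substr(chr[i], bad[i], bad[i]), bad[i], what, i))
  }
  out <- DNAStringSet(chr)
  if (!is.null(names(x))) names(out) <- names(x)
  if (is.null(names(out))) names(out) <- sprintf("seq%d", seq_along(out))
  out
}

#' Strand-variant transforms
#'
#' `seqComplement` maps A<->T, C<->G (N stays N), preserving order;
#' `seqInverse` reverses character order; `seqInverseComplement`
#' composes the two (the reverse complement). All accept character
#' vectors or `DNAStringSet`s and return a `DNAStringSet`.
#'
#' Naming note: "inverse" here means plain string reversal, so the
#' "complementary inverse" variant equals the conventional reverse
#' complement of the Watson strand.
#'
#' @param x sequences.
#' @return [Biostrings::DNAStringSet] of the transformed sequences.
#' @examples
#' as.character(seqComplement("AGCCT"))          # "TCGGA"
#' as.character(seqInverseComplement("AGCCT"))   # "AGGCT"
#' @export
seqComplement <- function(x) complement(asDNA(x))

#' @rdname seqComplement
#' @export
seqInverse <- function(x) reverse(asDNA(x))

#' @rdname seqComplement
#' @export
seqInverseComplement <- function(x) reverseComplement(asDNA(x))

.VARIANTS <- c("original", "complement", "inverse", "inverse_complement")

.applyVariant <- function(dna, tag) {
  switch(tag,
         original = dna,
         complement = complement(dna),
         inverse = reverse(dna),
         inverse_complement = reverseComplement(dna),
         stop("unknown strand variant '", tag, "'"))
}

#' Build the combined four-strand sequence
#'
#' Concatenates each sequence with its three strand variants
#' (complement, reversal, reverse complement) in a configurable order,
#' producing a sequence of four times the source length; a 200 bp input
#' yields an 800 bp combined sequence. The order is recorded in the
#' result's metadata so an experiment can be reproduced exactly.
#'
#' @param x sequences (character or `DNAStringSet`).
#' @param order permutation of
#'   `c("original", "complement", "inverse", "inverse_complement")`.
#' @return [Biostrings::DNAStringSet] of width `4 * width(x)`, with
#'   `metadata(.)$order` recording the concatenation order.
#' @examples
#' width(buildCombined(paste(rep("A", 200), collapse = "")))  # 800
#' as.character(buildCombined("A"))                           # "ATAT"
#' @export
buildCombined <- function(x, order = .VARIANTS) {
  dna <- asDNA(x)
  if (length(order) != 4L || anyDuplicated(order) ||
      !setequal(order, .VARIANTS))
    stop("'order' must be a permutation of: ", paste(.VARIANTS, collapse = ", "))
  parts <- lapply(order, function(tag) as.character(.applyVariant(dna, tag)))
  combined <- DNAStringSet(do.call(paste0, parts))
  names(combined) <- names(dna)
  metadata(combined)$order <- order
  combined
}

.tokenizeOne <- function(chr, k, s) {
  l <- nchar(chr)
  if (l < k)
    stop(sprintf("sequence of length %d is shorter than k = %d: no k-mers can be produced",
                 l, k))
  starts <- seq.int(1L, l - k + 1L, by = s)
  substring(chr, starts, starts + k - 1L)
}

#' Segment sequences into k-mer sentences
#'
#' Slides a window of size `k` with stride `s` over each sequence and
#' emits the ordered token list ("sentence"). A sequence of length l
#' yields `floor((l - k) / s) + 1` tokens; with `s = 1` that is
#' `l - k + 1` (e.g. AGCCT at k = 3 gives AGC, GCC, CCT, and an 800 bp
#' combined sequence gives 798 tokens). Tokenizing a combined sequence
#' deliberately spans the variant junctions: the combined string is one
#' sentence.
#'
#' @param x sequences (character, `DNAString(Set)`) or a single string.
#' @param k integer k-mer length (>= 1).
#' @param s integer stride (>= 1).
#' @param dropN drop tokens containing N. Default `FALSE`: keeping them
#'   preserves the fixed sentence-length contract.
#' @return a [KmerCorpus-class]; for a single unnamed character string,
#'   the token character vector.
#' @examples
#' kmerTokenize("AGCCT", k = 3, s = 1)   # "AGC" "GCC" "CCT"
#' @export
kmerTokenize <- function(x, k = 3L, s = 1L, dropN = FALSE) {
  k <- as.integer(k); s <- as.integer(s)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  if (is.na(s) || s < 1L) stop("s must be an integer >= 1")
  scalar <- is.character(x) && length(x) == 1L && is.null(names(x))
  dna <- asDNA(x)
  chr <- as.character(dna)
  toks <- lapply(chr, .tokenizeOne, k = k, s = s)
  if (dropN) toks <- lapply(toks, function(t) t[!grepl("N", t, fixed = TRUE)])
  if (scalar) return(toks[[1]])
  new("KmerCorpus", sentences = toks, k = k, s = s, ids = names(dna))
}

#' Tokenized corpus for a sequence collection
#'
#' Convenience wrapper: optionally builds the combined four-strand
#' sequence for every input, then tokenizes each into one sentence.
#'
#' @param x sequences (character or `DNAStringSet`), non-empty.
#' @param k,s k-mer length and stride, see [kmerTokenize()].
#' @param combined apply [buildCombined()] first (default `TRUE`).
#' @param order variant order for [buildCombined()].
#' @param dropN see [kmerTokenize()].
#' @return a [KmerCorpus-class], one sentence per input sequence.
#' @export
buildCorpus <- function(x, k = 3L, s = 1L, combined = TRUE,
                        order = .VARIANTS, dropN = FALSE) {
  dna <- asDNA(x)
  if (length(dna) == 0L) stop("empty input: no sequences to tokenize")
  if (combined) dna <- buildCombined(dna, order = order)
  corp <- kmerTokenize(dna, k = k, s = s, dropN = dropN)
  corp
}

#' Read/write a tokenized corpus
#'
#' Plain-text interchange format: one sentence per line, tokens
#' separated by single spaces.
#'
#' @param corpus a [KmerCorpus-class].
#' @param path file path.
#' @return `readCorpus` returns a [KmerCorpus-class]; ids are taken as
#'   line numbers.
#' @param k,s provenance to attach on read.
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "KmerCorpus"))
  writeLines(vapply(corpus@sentences, paste, character(1), collapse = " "),
             path)
  invisible(path)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(path, k, s = 1L) {
  lines <- readLines(path)
  toks <- strsplit(lines, " ", fixed = TRUE)
  new("KmerCorpus", sentences = toks, k = as.integer(k), s = as.integer(s),
      ids = sprintf("line%d", seq_along(toks)))
}
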