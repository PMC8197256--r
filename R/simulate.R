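#' Construct a PWM motif model
#'
#' @param pwm matrix (positions x 4), columns A, C, G, T, rows summing
#'   to 1.
#' @param name motif label.
#' @return a [MotifModel-class].
#' @export
motifModel <- function(pwm, name = "motif") {
  colnames(pwm) <- c("A", "C", "G", "T")
  new("MotifModel", pwm = pwm, name = name)
}

#' Bundled default motif
#'
#' A 12-column PWM with per-column maximum probability 0.85 (0.05 on
#' the other three bases): strong enough to be learnable in 20 epochs
#' at a few hundred positives, weak enough that featurizer comparisons
#' stay non-degenerate. Consensus TGACGTCATGCA.
#'
#' @return a [MotifModel-class].
#' @export
defaultMotif <- function() {
  consensus <- strsplit("TGACGTCATGCA", "")[[1]]
  pwm <- matrix(0.05, nrow = length(consensus), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) pwm[i, consensus[i]] <- 0.85
  motifModel(pwm, name = "synthetic12")
}

#' Sample background sequences
#'
#' i.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param n number of sequences.
#' @param length sequence length in bp.
#' @param gc target GC fraction in \[0, 1\].
#' @param seed optional RNG seed.
#' @return a [Biostrings::DNAStringSet].
#' @export
sampleBackground <- function(n = 1L, length = 200L, gc = 0.5, seed = NULL) {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- DNAStringSet(vapply(seq_len(n), function(i) .sampleIID(length, gc),
                             character(1)))
  names(out) <- sprintf("bg_%d", seq_len(n))
  out
}

.samplePWMInstance <- function(pwm) {
  paste(apply(pwm, 1, function(p) sample(c("A", "C", "G", "T"), 1L, prob = p)),
        collapse = "")
}

#' Implant a motif instance into sequences
#'
#' For each sequence, samples a motif instance column-wise from the
#' PWM, reverse-complements it with probability `rcProb` (both strands
#' of the double helix can carry a site), and writes it over a window
#' at a position drawn from `positionLaw`. Sequence length is
#' unchanged.
#'
#' @param x sequences (character or `DNAStringSet`).
#' @param motif a [MotifModel-class].
#' @param positionLaw "uniform" over all valid offsets, or "center"
#'   (binomial concentration around the middle).
#' @param rcProb probability of implanting the reverse complement.
#' @param seed optional RNG seed.
#' @return list with `sequences` (`DNAStringSet`) and `truth`
#'   (data.frame: id, start, strand).
#' @export
implantMotif <- function(x, motif, positionLaw = c("uniform", "center"),
                         rcProb = 0.5, seed = NULL) {
  positionLaw <- match.arg(positionLaw)
  stopifnot(is(motif, "MotifModel"))
  if (!is.null(seed)) set.seed(seed)
  dna <- asDNA(x)
  m <- nrow(motif@pwm)
  L <- width(dna)
  if (any(L < m)) stop("sequence shorter than motif")
  chr <- as.character(dna)
  nvalid <- L - m + 1L
  starts <- if (positionLaw == "uniform")
    vapply(nvalid, function(nv) sample.int(nv, 1L), integer(1))
  else 1L + rbinom(length(dna), nvalid - 1L, 0.5)
  strand <- ifelse(runif(length(dna)) < rcProb, "-", "+")
  for (i in seq_along(chr)) {
    inst <- .samplePWMInstance(motif@pwm)
    if (strand[i] == "-")
      inst <- as.character(reverseComplement(DNAStringSet(inst)))
    substr(chr[i], starts[i], starts[i] + m - 1L) <- inst
  }
  out <- DNAStringSet(chr)
  names(out) <- names(dna)
  list(sequences = out,
       truth = data.frame(id = names(dna), start = starts, strand = strand,
                          stringsAsFactors = FALSE))
}

#' Simulate a motif-implanted labeled dataset
#'
#' Emulates the benchmark construction: `nPos` fixed-length background
#' sequences each receive one PWM motif instance (either strand,
#' position drawn from `positionLaw`); `ratio * nPos` negatives are
#' drawn from the same background law without an implant and GC-matched
#' to their partner positives via [generateMatchedNegatives()]. The
#' ground-truth implant table (id, start, strand) is stored in the
#' result's `meta$truth`.
#'
#' @param nPos number of positives (default 500).
#' @param ratio negatives per positive, 1, 2 or 3 (default 1).
#' @param seqLength sequence length in bp (default 200).
#' @param gc background GC fraction (default 0.5).
#' @param motif a [MotifModel-class] (default [defaultMotif()]).
#' @param positionLaw implant position law, see [implantMotif()].
#' @param gcTolerance per-sequence GC matching tolerance (default 0.02).
#' @param seed master RNG seed (default 1).
#' @return a [LabeledSeqSet-class] with `meta$truth` and `meta$seed`.
#' @export
simulateDataset <- function(nPos = 500L, ratio = 1L, seqLength = 200L,
                            gc = 0.5, motif = defaultMotif(),
                            positionLaw = "uniform", gcTolerance = 0.02,
                            seed = 1L) {
  if (nPos < 1L) stop("nPos must be >= 1")
  if (seqLength < nrow(motif@pwm)) stop("seqLength shorter than motif")
  set.seed(seed)
  bg <- sampleBackground(nPos, seqLength, gc)
  imp <- implantMotif(bg, motif, positionLaw = positionLaw)
  pos <- imp$sequences
  names(pos) <- sprintf("pos_%d", seq_len(nPos))
  imp$truth$id <- names(pos)
  neg <- generateMatchedNegatives(pos, ratio = ratio, sampler = "iid",
                                  gcTolerance = gcTolerance)
  labeledSeqSet(pos, neg,
                meta = list(truth = imp$truth, seed = seed, gc = gc,
                            motif = motif@name, positionLaw = positionLaw))
}
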