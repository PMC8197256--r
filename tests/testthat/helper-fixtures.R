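library(Biostrings)

# random valid DNA string
randomDNA <- function(l, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, l, replace = TRUE), collapse = "")
}

# independent brute-force k-mer enumerator (string indexing only)
bruteKmers <- function(chr, k, s) {
  out <- character(0)
  i <- 1L
  while (i + k - 1L <= nchar(chr)) {
    out <- c(out, substr(chr, i, i + k - 1L))
    i <- i + s
  }
  out
}

# small labeled set with a perfectly separable composition signal
separableSet <- function(nPerClass = 30L, len = 40L) {
  pos <- DNAStringSet(setNames(
    vapply(seq_len(nPerClass), function(i) randomDNA(len, c("G", "C")),
           character(1)), sprintf("p%d", seq_len(nPerClass))))
  neg <- DNAStringSet(setNames(
    vapply(seq_len(nPerClass), function(i) randomDNA(len, c("A", "T")),
           character(1)), sprintf("n%d", seq_len(nPerClass))))
  labeledSeqSet(pos, neg)
}

# tiny bi-LSTM parameter list for the step oracle
randomLstmParams <- function(H, d) {
  rm <- function(r, c) matrix(rnorm(r * c, sd = 0.5), r, c)
  list(Wf = rm(H, d), Wi = rm(H, d), Wc = rm(H, d), Wo = rm(H, d),
       Uf = rm(H, H), Ui = rm(H, H), Uc = rm(H, H), Uo = rm(H, H),
       bf = rnorm(H, sd = 0.5), bi = rnorm(H, sd = 0.5),
       bc = rnorm(H, sd = 0.5), bo = rnorm(H, sd = 0.5))
}

zeroLstmParams <- function(H, d) {
  z <- function(r, c) matrix(0, r, c)
  list(Wf = z(H, d), Wi = z(H, d), Wc = z(H, d), Wo = z(H, d),
       Uf = z(H, H), Ui = z(H, H), Uc = z(H, H), Uo = z(H, H),
       bf = numeric(H), bi = numeric(H), bc = numeric(H), bo = numeric(H))
}

# scalar-loop oracle for one LSTM step: no matrix ops, plain sums
scalarLstmStep <- function(x, hPrev, cPrev, p) {
  H <- length(hPrev)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H); cc <- numeric(H)
  for (r in seq_len(H)) {
    af <- p$bf[r]; ai <- p$bi[r]; ac <- p$bc[r]; ao <- p$bo[r]
    for (j in seq_along(x)) {
      af <- af + p$Wf[r, j] * x[j]; ai <- ai + p$Wi[r, j] * x[j]
      ac <- ac + p$Wc[r, j] * x[j]; ao <- ao + p$Wo[r, j] * x[j]
    }
    for (j in seq_len(H)) {
      af <- af + p$Uf[r, j] * hPrev[j]; ai <- ai + p$Ui[r, j] * hPrev[j]
      ac <- ac + p$Uc[r, j] * hPrev[j]; ao <- ao + p$Uo[r, j] * hPrev[j]
    }
    f <- sig(af); i <- sig(ai); g <- tanh(ac); o <- sig(ao)
    cc[r] <- f * cPrev[r] + i * g
    h[r] <- o * tanh(cc[r])
  }
  list(h = h, c = cc)
}

# confusion-matrix arithmetic oracle for PR AUC (threshold sweep over
# distinct scores, step sum) and F1
oraclePR <- function(labels, scores) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  rec0 <- 0; auc <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / P
    auc <- auc + (rec - rec0) * prec
    rec0 <- rec
  }
  auc
}

oracleF1 <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
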