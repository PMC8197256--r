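.checkScores <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  labels
}

#' ROC AUC
#'
#' Probability that a uniformly drawn positive outranks a uniformly
#' drawn negative, with ties counted one half (the rank-sum / Mann-
#' Whitney formulation).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return numeric in \[0, 1\].
#' @examples
#' rocAUC(c(1, 1, 0, 0), c(0.8, 0.3, 0.5, 0.1))  # 0.75
#' @export
rocAUC <- function(labels, scores) {
  labels <- .checkScores(labels, scores)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Precision-recall AUC
#'
#' Area under the precision-recall curve by the precision-weighted
#' recall-step sum: thresholds sweep the distinct scores in descending
#' order (tied scores enter together) and each recall increment is
#' weighted by the precision at that threshold.
#'
#' @inheritParams rocAUC
#' @return numeric in (0, 1].
#' @export
prAUC <- function(labels, scores) {
  labels <- .checkScores(labels, scores)
  P <- sum(labels == 1L)
  if (P == 0L) stop("PR AUC undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab); fp <- cumsum(1L - lab)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' F1 score at a threshold
#'
#' Harmonic mean of precision and recall for the hard classification
#' `score >= threshold`; 0 by convention when nothing is predicted
#' positive or nothing is recovered.
#'
#' @inheritParams rocAUC
#' @param threshold decision threshold (default 0.5).
#' @return numeric in \[0, 1\].
#' @export
f1Score <- function(labels, scores, threshold = 0.5) {
  labels <- .checkScores(labels, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (tp == 0L) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Metrics report for a score vector
#'
#' @inheritParams f1Score
#' @return a [MetricsReport-class].
#' @export
evaluateScores <- function(labels, scores, threshold = 0.5) {
  labels <- .checkScores(labels, scores)
  new("MetricsReport", rocAUC = rocAUC(labels, scores),
      prAUC = prAUC(labels, scores),
      f1 = f1Score(labels, scores, threshold), threshold = threshold,
      nPos = sum(labels == 1L), nNeg = sum(labels == 0L))
}

#' @rdname evaluateScores
#' @param report a [MetricsReport-class] (or list of them).
#' @return `metricsTable` returns a one-row (or n-row) data.frame.
#' @export
metricsTable <- function(report) {
  if (is.list(report))
    return(do.call(rbind, lapply(report, metricsTable)))
  data.frame(rocAUC = report@rocAUC, prAUC = report@prAUC, f1 = report@f1,
             threshold = report@threshold, nPos = report@nPos,
             nNeg = report@nNeg)
}
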