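# Evaluation metrics: rank-based AUC, macro/micro F1, precision-at-k,
# accuracy, and a bundled report.

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic: the probability
#' that a random positive outranks a random negative, ties counting one half.
#'
#' @param scores numeric score vector.
#' @param truth binary 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth) {
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_argument("AUC undefined: truth contains a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro and micro F1
#'
#' Macro F1 averages per-class F1 (classes with zero true positives, false
#' positives and false negatives -- i.e. absent and never predicted -- score
#' 0, as do classes where precision + recall is 0); micro F1 pools TP/FP/FN
#' counts over all classes first.
#'
#' @param pred binary prediction matrix (samples x classes), or vector.
#' @param truth binary truth matrix of the same shape.
#' @return List with `macro` and `micro`.
#' @export
f1_scores <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  stopifnot(all(dim(pred) == dim(truth)))
  tp <- colSums(pred == 1 & truth == 1)
  fp <- colSums(pred == 1 & truth == 0)
  fn <- colSums(pred == 0 & truth == 1)
  f1c <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  micro <- if (sum(2 * tp + fp + fn) > 0) 2 * sum(tp) / sum(2 * tp + fp + fn) else 0
  list(macro = mean(f1c), micro = micro)
}

#' Precision at k
#'
#' Mean over samples of the fraction of true labels among the k top-scoring
#' predicted labels. Score ties are broken by label index (lower index
#' first).
#'
#' @param scores score matrix (samples x labels).
#' @param truth binary truth matrix of the same shape.
#' @param k number of top predictions to consider (`1 <= k <=` number of
#'   labels).
#' @return P@k in `[0, 1]`.
#' @export
precision_at_k <- function(scores, truth, k) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  C <- ncol(scores)
  if (k < 1 || k > C) stop_argument("k must lie in 1..C")
  hits <- vapply(seq_len(nrow(scores)), function(i) {
    top <- order(-scores[i, ], seq_len(C))[seq_len(k)]
    sum(truth[i, top])
  }, numeric(1))
  mean(hits / k)
}

#' Classification accuracy
#'
#' Fraction of correct predictions.
#'
#' @param pred predicted labels (vector or matrix).
#' @param truth true labels of the same shape.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0) stop_argument("empty input")
  stopifnot(length(pred) == length(truth))
  mean(pred == truth)
}

#' Bundled metrics report
#'
#' Computes macro/micro AUC (macro skips classes whose truth is single-class
#' and reports how many were skipped), macro/micro F1 at a 0.5 threshold,
#' P@k for each requested k, and element-wise accuracy of the thresholded
#' predictions.
#'
#' @param Z probability/score matrix (samples x labels).
#' @param Y binary truth matrix.
#' @param ks integer vector of k values for P@k.
#' @param threshold binarization threshold for F1/accuracy (default 0.5).
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(Z, Y, ks = c(1L, 5L), threshold = 0.5) {
  Z <- as.matrix(Z); Y <- as.matrix(Y)
  usable <- which(colSums(Y == 1) > 0 & colSums(Y == 0) > 0)
  auc_macro <- if (length(usable)) {
    mean(vapply(usable, function(c) auc(Z[, c], Y[, c]), numeric(1)))
  } else NA_real_
  auc_micro <- if (length(unique(as.vector(Y))) == 2) auc(as.vector(Z), as.vector(Y)) else NA_real_
  P <- (Z >= threshold) * 1
  f1 <- f1_scores(P, Y)
  ks <- ks[ks <= ncol(Z)]
  pk <- vapply(ks, function(k) precision_at_k(Z, Y, k), numeric(1))
  names(pk) <- paste0("p_at_", ks)
  structure(list(auc_macro = auc_macro, auc_micro = auc_micro,
                 auc_classes_skipped = ncol(Y) - length(usable),
                 f1_macro = f1$macro, f1_micro = f1$micro,
                 p_at_k = pk, accuracy = accuracy(P, Y), ks = ks),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC  macro %.4f / micro %.4f (skipped %d degenerate classes)\n",
              x$auc_macro, x$auc_micro, x$auc_classes_skipped))
  cat(sprintf("F1   macro %.4f / micro %.4f\n", x$f1_macro, x$f1_micro))
  for (i in seq_along(x$p_at_k))
    cat(sprintf("P@%-2d %.4f\n", x$ks[i], x$p_at_k[i]))
  cat(sprintf("Acc  %.4f\n", x$accuracy))
  invisible(x)
}
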