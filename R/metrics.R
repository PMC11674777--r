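# Evaluation suite: one-vs-rest confusion counts, per-class and
# micro-averaged precision/recall/F1, accuracy, and micro ROC-AUC.
# Zero-denominator metrics are reported as 0 with a "defined" flag rather
# than raising, so batch evaluation never aborts.

check_label_pair <- function(truth, pred, K) {
  truth <- check_class_indices(truth, K, "truth label")
  pred <- check_class_indices(pred, K, "predicted label")
  if (length(truth) != length(pred))
    stop_cf("truth and prediction lengths differ: %d vs %d",
            length(truth), length(pred), class = "cf_validation_error")
  if (length(truth) < 1L)
    stop_cf("need at least one sample", class = "cf_validation_error")
  list(truth = truth, pred = pred)
}

#' One-vs-rest confusion counts
#'
#' For each class k in turn treated as "positive" against all others,
#' tallies TP, FP, FN and TN over a pair of label sequences. For every
#' class \code{TP + FP + FN + TN = N}, and the TP column sums to the
#' number of exactly correct predictions.
#'
#' @param truth Integer vector of true class indices (1-based).
#' @param pred Integer vector of predicted class indices, same length.
#' @param K Number of classes.
#' @return A \code{confusion_counts} object: K x 4 integer matrix with
#'   columns TP, FP, FN, TN and attribute \code{n}.
#' @export
confusion_counts <- function(truth, pred, K) {
  lp <- check_label_pair(truth, pred, K)
  n <- length(lp$truth)
  # K x K contingency table: rows = truth, cols = prediction
  tab <- matrix(0L, K, K)
  for (i in seq_len(n))
    tab[lp$truth[i], lp$pred[i]] <- tab[lp$truth[i], lp$pred[i]] + 1L
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  tn <- n - tp - fp - fn
  counts <- cbind(TP = tp, FP = fp, FN = fn, TN = tn)
  rownames(counts) <- NULL
  structure(counts, n = n, class = c("confusion_counts", class(counts)))
}

#' Per-class precision, recall and F1
#'
#' precision_k = TP/(TP+FP), recall_k = TP/(TP+FN), F1 = harmonic mean of
#' the two. A zero denominator yields the value 0 together with a FALSE
#' \code{*_defined} flag instead of NaN or an error.
#'
#' @param counts A \code{\link{confusion_counts}} object.
#' @return Data frame with one row per class: precision, recall, f1 and
#'   the corresponding \code{*_defined} logical flags.
#' @export
per_class_prf <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts[, "TP"]; fp <- counts[, "FP"]; fn <- counts[, "FN"]
  safe_div <- function(num, den) ifelse(den > 0, num / pmax(den, 1), 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  f1_den <- precision + recall
  f1 <- ifelse(f1_den > 0, 2 * precision * recall / f1_den, 0)
  f1_def <- p_def & r_def & f1_den > 0
  data.frame(class = seq_len(nrow(counts)),
             precision = precision, precision_defined = p_def,
             recall = recall, recall_defined = r_def,
             f1 = f1, f1_defined = f1_def)
}

#' Classification accuracy
#'
#' Proportion of samples whose predicted class equals the true class
#' (the multi-class reading of the binary TP+TN over total form; its
#' one-vs-rest average duplicates the micro metrics).
#'
#' @param truth,pred Equal-length label sequences.
#' @return Proportion in [0, 1].
#' @export
accuracy <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) < 1L)
    stop_cf("truth and prediction must be equal-length, non-empty",
            class = "cf_validation_error")
  mean(truth == pred)
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP, FP and FN over all classes before applying the precision,
#' recall and F1 formulas. For single-label multi-class predictions every
#' false positive for one class is a false negative for another, so
#' pooled FP equals pooled FN and micro precision, recall, F1 and
#' accuracy all coincide.
#'
#' @param counts A \code{\link{confusion_counts}} object.
#' @return List with \code{precision}, \code{recall}, \code{f1}.
#' @export
micro_average <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- sum(counts[, "TP"]); fp <- sum(counts[, "FP"]); fn <- sum(counts[, "FN"])
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

# Binary AUC by the rank (Mann-Whitney) construction; ties count 1/2.
auc_rank <- function(scores, positive) {
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Micro-averaged ROC-AUC
#'
#' Flattens the N x K one-hot truth matrix and the N x K score matrix
#' into N*K binary decisions and computes the probability that a
#' positive cell outscores a negative cell, ties counted one half
#' (equivalently, trapezoidal area under the micro ROC curve).
#'
#' @param truth Integer vector of N true class indices (1-based).
#' @param probs Numeric N x K score matrix.
#' @return AUC in [0, 1].
#' @export
roc_auc_micro <- function(truth, probs) {
  probs <- as.matrix(probs)
  K <- ncol(probs)
  truth <- check_class_indices(truth, K, "truth label")
  if (length(truth) != nrow(probs))
    stop_cf("truth length %d does not match %d rows", length(truth), nrow(probs),
            class = "cf_validation_error")
  if (nrow(probs) < 2L)
    stop_cf("micro ROC-AUC needs at least 2 samples", class = "cf_validation_error")
  onehot <- matrix(FALSE, nrow(probs), K)
  onehot[cbind(seq_len(nrow(probs)), truth)] <- TRUE
  auc <- auc_rank(as.vector(probs), as.vector(onehot))
  if (is.na(auc))
    stop_cf("degenerate one-vs-rest expansion: no positives or no negatives",
            class = "cf_undefined_metric_error")
  auc
}

#' Per-class one-vs-rest ROC-AUC
#'
#' @param truth Integer vector of true class indices.
#' @param probs Numeric N x K score matrix.
#' @return Numeric vector of K AUCs; classes absent from (or covering all
#'   of) the truth yield NA.
#' @export
roc_auc_per_class <- function(truth, probs) {
  probs <- as.matrix(probs)
  K <- ncol(probs)
  truth <- check_class_indices(truth, K, "truth label")
  vapply(seq_len(K), function(k) auc_rank(probs[, k], truth == k), numeric(1L))
}
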