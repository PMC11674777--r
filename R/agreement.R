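# Scott's Pi: chance-corrected agreement between two label streams, with
# chance agreement computed from the POOLED marginal distribution of both
# streams (this pooling is what distinguishes pi from Cohen's kappa; the
# two coincide when the raters' marginals are identical). Ordinal
# weighting credits near-misses by class distance.

agreement_weight_matrix <- function(K, weighting) {
  d <- abs(outer(seq_len(K), seq_len(K), "-"))
  switch(weighting,
         none = (d == 0) * 1,
         linear = 1 - d / (K - 1),
         quadratic = 1 - (d / (K - 1))^2,
         stop_cf("unknown weighting '%s'", weighting, class = "cf_validation_error"))
}

#' Scott's Pi agreement between two label streams
#'
#' pi = (Po - Pe) / (1 - Pe), where Po is the observed agreement
#' proportion and Pe the agreement expected by chance under the pooled
#' marginal m_k = (count_a(k) + count_b(k)) / (2N). Unweighted agreement
#' is exact-match; the ordinal variants replace the agreement indicator
#' with 1 - |i-j|/(K-1) (linear) or 1 - ((i-j)/(K-1))^2 (quadratic) in
#' both Po and Pe, so adjacent-stage confusions are penalized less than
#' distant ones. Symmetric in its two arguments.
#'
#' When both streams are concentrated on a single common class, Pe = 1
#' and pi is undefined; the result carries \code{defined = FALSE} with
#' \code{pi = NA} rather than raising.
#'
#' @param a,b Equal-length integer label sequences (1-based indices).
#' @param K Number of classes.
#' @param weighting One of "none" (default), "linear", "quadratic".
#' @return An \code{agreement_result}: list with \code{po}, \code{pe},
#'   \code{pi}, \code{defined}, \code{weighting}.
#' @examples
#' scotts_pi(c(1, 1, 2, 2), c(1, 2, 2, 2), K = 2)  # pi = 7/15
#' @export
scotts_pi <- function(a, b, K, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  lp <- check_label_pair(a, b, K)
  a <- lp$truth; b <- lp$pred
  n <- length(a)
  w <- agreement_weight_matrix(K, weighting)
  po <- mean(w[cbind(a, b)])
  m <- (tabulate(a, K) + tabulate(b, K)) / (2 * n)
  pe <- as.numeric(t(m) %*% w %*% m)
  defined <- (1 - pe) > .Machine$double.eps^0.5
  structure(list(po = po, pe = pe,
                 pi = if (defined) (po - pe) / (1 - pe) else NA_real_,
                 defined = defined, weighting = weighting),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Scott's Pi (%s weighting): Po = %.6f, Pe = %.6f, pi = %s\n",
              x$weighting, x$po, x$pe,
              if (x$defined) sprintf("%.6f", x$pi) else "undefined (Pe = 1)"))
  invisible(x)
}

#' Pairwise model-agreement matrix
#'
#' Computes Scott's Pi between the argmax label streams of every pair of
#' aligned prediction sets: the analysis used to pick complementary
#' models for an ensemble. Diagonal entries are self-agreement (1 when
#' defined, NA for a degenerate constant stream).
#'
#' @param models List of 2 or more aligned \code{\link{prediction_set}}s.
#' @param weighting Passed to \code{\link{scotts_pi}}.
#' @return Symmetric numeric matrix with model ids as dimnames.
#' @export
agreement_matrix <- function(models, weighting = "none") {
  assert_aligned(models)
  ids <- vapply(models, function(m) m$model_id, character(1L))
  labs <- lapply(models, function(m) argmax_labels(m$probs))
  K <- models[[1L]]$scheme$K
  M <- length(models)
  out <- matrix(NA_real_, M, M, dimnames = list(ids, ids))
  for (i in seq_len(M)) for (j in i:M) {
    r <- scotts_pi(labs[[i]], labs[[j]], K, weighting)
    out[i, j] <- out[j, i] <- if (r$defined) r$pi else NA_real_
  }
  out
}

#' Full metrics report for one prediction stream
#'
#' Ties the suite together: per-class precision/recall/F1, micro
#' averages, accuracy, micro and per-class ROC-AUC, and Scott's Pi of the
#' argmax labels against the truth.
#'
#' @param truth Integer vector of true class indices.
#' @param probs N x K score matrix (raw probabilities or fused weighted
#'   sums; AUC and argmax are scale-invariant per row set).
#' @param scheme A \code{\link{class_scheme}}.
#' @param weighting Scott's Pi weighting, default "none".
#' @return A \code{metrics_report}: list with \code{per_class} (data
#'   frame), \code{micro}, \code{accuracy}, \code{roc_auc_micro},
#'   \code{roc_auc_per_class}, \code{scotts_pi_vs_truth}.
#' @export
metrics_report <- function(truth, probs, scheme, weighting = "none") {
  stopifnot(inherits(scheme, "class_scheme"))
  probs <- as.matrix(probs)
  pred <- argmax_labels(probs)
  counts <- confusion_counts(truth, pred, scheme$K)
  prf <- per_class_prf(counts)
  prf$class <- scheme$names
  pi_res <- scotts_pi(truth, pred, scheme$K, weighting)
  structure(
    list(per_class = prf,
         micro = micro_average(counts),
         accuracy = accuracy(truth, pred),
         roc_auc_micro = roc_auc_micro(truth, probs),
         roc_auc_per_class = stats::setNames(roc_auc_per_class(truth, probs),
                                             scheme$names),
         scotts_pi_vs_truth = pi_res,
         weighting = weighting),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics:\n")
  print(x$per_class[, c("class", "precision", "recall", "f1")], digits = 4)
  cat(sprintf("Micro-average: P = R = F1 = %.4f (accuracy %.4f)\n",
              x$micro$f1, x$accuracy))
  cat(sprintf("Micro ROC-AUC: %.4f\n", x$roc_auc_micro))
  cat(sprintf("Scott's Pi vs truth (%s): %s\n", x$weighting,
              if (x$scotts_pi_vs_truth$defined)
                sprintf("%.5f", x$scotts_pi_vs_truth$pi) else "undefined"))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A \code{\link{metrics_report}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  pi_res <- report$scotts_pi_vs_truth
  jsonlite::write_json(
    list(per_class = report$per_class,
         micro = report$micro,
         accuracy = report$accuracy,
         roc_auc_micro = report$roc_auc_micro,
         roc_auc_per_class = as.list(report$roc_auc_per_class),
         scotts_pi_vs_truth = list(po = pi_res$po, pe = pi_res$pe,
                                   pi = pi_res$pi, defined = pi_res$defined,
                                   weighting = pi_res$weighting)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write an agreement matrix as CSV
#'
#' Model ids appear both as the header row and as the first column.
#'
#' @param mat Matrix from \code{\link{agreement_matrix}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_agreement_matrix <- function(mat, path) {
  df <- data.frame(model = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
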