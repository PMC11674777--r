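# Soft-voting fusion: combine per-model class probabilities by simple or
# weighted averaging. Weighted rows sum to sum(w), not 1, and are used as-is
# (no renormalization): only the argmax is consumed downstream, and the
# decision is invariant to positive rescaling of the weight vector.

check_weights <- function(w, n_models = NULL) {
  w <- as.numeric(w)
  if (length(w) < 2L)
    stop_cf("a weight vector needs at least 2 entries, got %d", length(w),
            class = "cf_weight_error")
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop_cf("weights must be finite and in [0, 1]", class = "cf_weight_error")
  if (all(w == 0))
    stop_cf("at least one weight must be positive", class = "cf_weight_error")
  if (!is.null(n_models) && length(w) != n_models)
    stop_cf("%d weights for %d models", length(w), n_models,
            class = "cf_dimension_error")
  w
}

#' Row-wise argmax class labels
#'
#' Decision rule applied to fused (or raw) score matrices: each sample is
#' assigned the class with the largest score. Ties are broken toward the
#' lowest class index, i.e. the least severe stage — a deterministic and
#' clinically conservative rule.
#'
#' @param probs Numeric N x K matrix of non-negative scores.
#' @return Integer vector of N class indices (1-based).
#' @export
argmax_labels <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L || ncol(probs) < 1L)
    stop_cf("empty score matrix", class = "cf_dimension_error")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop_cf("scores must be finite and non-negative", class = "cf_validation_error")
  max.col(probs, ties.method = "first")
}

#' Weighted soft-voting fusion
#'
#' Combines M aligned prediction sets into one prediction stream:
#' \code{probs[i,k] = sum_m w[m] * probs_m[i,k]}. Fused rows sum to
#' \code{sum(w)} (weights need not sum to one) and are deliberately not
#' renormalized; predicted labels are the tie-broken row argmax.
#'
#' @param models List of 2 or more pairwise-aligned
#'   \code{\link{prediction_set}} objects.
#' @param weights Numeric vector, one weight in [0, 1] per model, at least
#'   one positive. No sum-to-one constraint.
#' @return A \code{fused_predictions} object: list with \code{probs},
#'   \code{labels}, \code{weights_used}, \code{source_model_ids},
#'   \code{sample_ids}, \code{truth} (if any model carried it) and
#'   \code{scheme}.
#' @seealso \code{\link{average_fuse}} for the equal-weight special case.
#' @export
weighted_fuse <- function(models, weights) {
  truth <- assert_aligned(models)
  w <- check_weights(weights, n_models = length(models))
  probs <- w[1L] * models[[1L]]$probs
  for (m in seq_along(models)[-1L])
    probs <- probs + w[m] * models[[m]]$probs
  structure(
    list(probs = probs,
         labels = argmax_labels(probs),
         weights_used = w,
         source_model_ids = vapply(models, function(m) m$model_id, character(1L)),
         sample_ids = models[[1L]]$sample_ids,
         truth = truth,
         scheme = models[[1L]]$scheme),
    class = "fused_predictions")
}

#' Simple-average fusion
#'
#' Element-wise mean of the model probability matrices: every model
#' contributes equally. Identical to \code{\link{weighted_fuse}} with all
#' weights \code{1/M}; fused rows sum to 1 when the inputs do.
#'
#' @param models List of 2 or more aligned \code{\link{prediction_set}}s.
#' @return A \code{fused_predictions} object.
#' @export
average_fuse <- function(models) {
  weighted_fuse(models, rep(1 / length(models), length(models)))
}

#' @export
print.fused_predictions <- function(x, ...) {
  cat("Fused predictions from (", paste(x$source_model_ids, collapse = ", "),
      ") with weights (", paste(format(x$weights_used), collapse = ", "),
      "): ", nrow(x$probs), " samples\n", sep = "")
  invisible(x)
}

#' Write fused predictions with a provenance sidecar
#'
#' The fused score matrix is written via
#' \code{\link{write_prediction_table}} after rescaling rows to unit sum
#' (required by the prediction-table contract; the rescaling does not
#' change argmax labels). A sidecar JSON next to the table records the raw
#' weights used and the source model ids.
#'
#' @param fused A \code{fused_predictions} object.
#' @param path Output CSV path; the sidecar is written to
#'   \code{paste0(path, ".meta.json")}.
#' @return Invisibly, \code{path}.
#' @export
write_fused_predictions <- function(fused, path) {
  stopifnot(inherits(fused, "fused_predictions"))
  ps <- prediction_set(paste(fused$source_model_ids, collapse = "+"),
                       fused$sample_ids, fused$probs / rowSums(fused$probs),
                       fused$scheme, truth = fused$truth)
  write_prediction_table(ps, path)
  jsonlite::write_json(
    list(weights_used = fused$weights_used,
         source_model_ids = fused$source_model_ids),
    paste0(path, ".meta.json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}
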