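#' Construct a prediction set
#'
#' A prediction set holds one model's N x K class-probability matrix,
#' together with sample identifiers and (optionally) the true class of each
#' sample. Rows must be probability vectors: every entry in [0, 1] and each
#' row summing to 1 within a tolerance of 1e-6. Out-of-tolerance rows are
#' rejected rather than silently renormalized; pass
#' \code{renormalize = TRUE} to explicitly opt in to rescaling.
#'
#' @param model_id Free-text identifier of the model that produced the
#'   probabilities.
#' @param sample_ids Character vector of N unique sample identifiers.
#' @param probs Numeric N x K matrix of class probabilities, columns in
#'   scheme order.
#' @param scheme A \code{\link{class_scheme}}.
#' @param truth Optional integer vector of N true class indices (1-based,
#'   in scheme order), or character vector of class names.
#' @param renormalize If TRUE, rows are rescaled to sum to exactly 1
#'   instead of raising an error when a row sum falls outside 1 +/- 1e-6.
#' @return An object of class \code{prediction_set}.
#' @export
prediction_set <- function(model_id, sample_ids, probs, scheme,
                           truth = NULL, renormalize = FALSE) {
  stopifnot(inherits(scheme, "class_scheme"))
  probs <- as.matrix(probs)
  storage.mode(probs) <- "double"
  sample_ids <- as.character(sample_ids)
  n <- nrow(probs)
  if (n < 1L)
    stop_cf("a prediction set needs at least one sample", class = "cf_validation_error")
  if (ncol(probs) != scheme$K)
    stop_cf("probability matrix has %d columns but scheme has K = %d classes",
            ncol(probs), scheme$K, class = "cf_validation_error")
  if (length(sample_ids) != n)
    stop_cf("%d sample ids for %d rows", length(sample_ids), n,
            class = "cf_validation_error")
  if (anyDuplicated(sample_ids))
    stop_cf("sample ids must be unique; duplicated: %s",
            paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 3), collapse = ", "),
            class = "cf_validation_error")
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop_cf("probabilities must be finite and in [0, 1]", class = "cf_validation_error")
  rs <- rowSums(probs)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad)) {
    if (renormalize) {
      probs <- probs / rs
    } else {
      stop_cf("row probabilities for sample '%s' sum to %.8g, outside 1 +/- 1e-6",
              sample_ids[bad[1L]], rs[bad[1L]], class = "cf_rowsum_error")
    }
  }
  if (!is.null(truth)) {
    if (is.character(truth) || is.factor(truth))
      truth <- scheme_index(scheme, truth)
    truth <- check_class_indices(truth, scheme$K, "truth label")
    if (length(truth) != n)
      stop_cf("truth has length %d, expected %d", length(truth), n,
              class = "cf_validation_error")
  }
  dimnames(probs) <- list(NULL, scheme$names)
  structure(
    list(model_id = as.character(model_id)[1L], sample_ids = sample_ids,
         probs = probs, truth = truth, scheme = scheme),
    class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("Prediction set '", x$model_id, "': ", nrow(x$probs), " samples x ",
      x$scheme$K, " classes", if (is.null(x$truth)) " (no truth)" else " (with truth)",
      "\n", sep = "")
  invisible(x)
}

#' Read a prediction table from CSV
#'
#' Expected header: \code{sample_id}, then optionally \code{true_label},
#' then one probability column per class in exact scheme order. Class
#' columns in a different order than the scheme are a format error (class
#' order is fixed by configuration, never inferred from files).
#'
#' @param path Path to a CSV file.
#' @param scheme A \code{\link{class_scheme}} fixing column order.
#' @param model_id Model identifier for the returned set; defaults to the
#'   file name without extension.
#' @param renormalize Passed to \code{\link{prediction_set}}.
#' @return A \code{\link{prediction_set}}; row order is preserved.
#' @export
read_prediction_table <- function(path, scheme, model_id = NULL,
                                  renormalize = FALSE) {
  if (!file.exists(path))
    stop_cf("prediction table not found: %s", path, class = "cf_io_error")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  cols <- names(df)
  if (length(cols) < 1L || cols[1L] != "sample_id")
    stop_cf("first column must be 'sample_id', found '%s'",
            if (length(cols)) cols[1L] else "<none>", class = "cf_format_error")
  has_truth <- length(cols) >= 2L && cols[2L] == "true_label"
  class_cols <- cols[(if (has_truth) 3L else 2L):length(cols)]
  expected <- scheme$names
  if (length(class_cols) != length(expected) || any(class_cols != expected)) {
    m <- min(length(class_cols), length(expected))
    mismatch <- which(class_cols[seq_len(m)] != expected[seq_len(m)])
    offender <- if (length(mismatch)) class_cols[mismatch[1L]]
                else if (length(class_cols) > length(expected)) class_cols[length(expected) + 1L]
                else expected[length(class_cols) + 1L]
    stop_cf("class columns must be exactly (%s) in order; mismatch at column '%s'",
            paste(expected, collapse = ", "), offender, class = "cf_format_error")
  }
  probs <- vapply(df[class_cols], as.numeric, numeric(nrow(df)))
  probs <- matrix(probs, nrow = nrow(df), ncol = length(class_cols))
  truth <- if (has_truth) df[["true_label"]] else NULL
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  prediction_set(model_id, df[["sample_id"]], probs, scheme,
                 truth = truth, renormalize = renormalize)
}

#' Write a prediction table to CSV
#'
#' Probabilities are written with 17 significant digits so that
#' \code{read_prediction_table(write_prediction_table(ps))} reproduces the
#' matrix bit-for-bit. Truth labels are stored as class names; the column
#' is omitted entirely when the set carries no truth.
#'
#' @param ps A \code{\link{prediction_set}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_prediction_table <- function(ps, path) {
  stopifnot(inherits(ps, "prediction_set"))
  fmt <- function(x) sub("^([0-9.eE+-]+)$", "\\1", sprintf("%.17g", x))
  out <- data.frame(sample_id = ps$sample_ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(ps$truth))
    out$true_label <- ps$scheme$names[ps$truth]
  for (k in seq_len(ps$scheme$K))
    out[[ps$scheme$names[k]]] <- fmt(ps$probs[, k])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_cf("cannot write prediction table to '%s': %s", path,
            conditionMessage(ok), class = "cf_io_error")
  invisible(path)
}

#' Check that two prediction sets are aligned
#'
#' Fusion requires that all models score the same samples in the same
#' order over the same classes, with consistent truth. This returns a
#' report rather than raising: fusion operations reject unaligned input
#' using the report's entries.
#'
#' @param a,b \code{\link{prediction_set}} objects.
#' @return An \code{alignment_report}: list with \code{ok} (logical) and
#'   \code{mismatches}, a data frame of (type, detail) rows.
#' @export
validate_prediction_pair <- function(a, b) {
  stopifnot(inherits(a, "prediction_set"), inherits(b, "prediction_set"))
  mm <- list()
  add <- function(type, detail)
    mm[[length(mm) + 1L]] <<- data.frame(type = type, detail = detail,
                                         stringsAsFactors = FALSE)
  if (a$scheme$K != b$scheme$K || !identical(a$scheme$names, b$scheme$names))
    add("scheme", sprintf("class schemes differ: (%s) vs (%s)",
                          paste(a$scheme$names, collapse = ","),
                          paste(b$scheme$names, collapse = ",")))
  na <- length(a$sample_ids); nb <- length(b$sample_ids)
  if (na != nb) {
    add("size", sprintf("sample counts differ: %d vs %d", na, nb))
  } else if (!identical(a$sample_ids, b$sample_ids)) {
    first <- which(a$sample_ids != b$sample_ids)[1L]
    if (setequal(a$sample_ids, b$sample_ids))
      add("order", sprintf("same ids in different order; first difference at position %d ('%s' vs '%s')",
                           first, a$sample_ids[first], b$sample_ids[first]))
    else
      add("ids", sprintf("sample ids differ; first difference at position %d ('%s' vs '%s')",
                         first, a$sample_ids[first], b$sample_ids[first]))
  } else if (!is.null(a$truth) && !is.null(b$truth)) {
    diff <- which(a$truth != b$truth)
    for (i in utils::head(diff, 10L))
      add("truth", sprintf("truth conflict at sample '%s': %s vs %s",
                           a$sample_ids[i], a$scheme$names[a$truth[i]],
                           b$scheme$names[b$truth[i]]))
  }
  mismatches <- if (length(mm)) do.call(rbind, mm)
                else data.frame(type = character(), detail = character(),
                                stringsAsFactors = FALSE)
  structure(list(ok = nrow(mismatches) == 0L, mismatches = mismatches),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  if (x$ok) cat("Aligned: no mismatches.\n")
  else {
    cat("NOT aligned:", nrow(x$mismatches), "mismatch(es)\n")
    for (i in seq_len(nrow(x$mismatches)))
      cat("  [", x$mismatches$type[i], "] ", x$mismatches$detail[i], "\n", sep = "")
  }
  invisible(x)
}

# Assert that a list of prediction sets is pairwise aligned; returns truth
# (possibly NULL) merged across models.
assert_aligned <- function(models) {
  if (length(models) < 2L)
    stop_cf("need at least 2 models, got %d", length(models),
            class = "cf_validation_error")
  for (m in models) stopifnot(inherits(m, "prediction_set"))
  for (i in seq_along(models)[-1L]) {
    rep <- validate_prediction_pair(models[[1L]], models[[i]])
    if (!rep$ok)
      stop(errorCondition(
        paste0("prediction sets '", models[[1L]]$model_id, "' and '",
               models[[i]]$model_id, "' are not aligned: ",
               paste(rep$mismatches$detail, collapse = "; ")),
        class = c("cf_alignment_error", "cuckoofuse_error"),
        report = rep))
  }
  truth <- NULL
  for (m in models) if (!is.null(m$truth)) { truth <- m$truth; break }
  truth
}
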