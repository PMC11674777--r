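#' Construct a dataset manifest
#'
#' A manifest maps sample ids to ordinal class labels, with a split tag
#' per entry from the closed set \{unassigned, test, train, validation\}.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param labels Integer class indices (1-based) or character class names.
#' @param scheme A \code{\link{class_scheme}}.
#' @param split Split tags, recycled if length 1; default "unassigned".
#' @return A \code{dataset_manifest}: a data frame with columns
#'   \code{sample_id}, \code{label} (integer index) and \code{split}, plus
#'   the scheme as an attribute.
#' @export
dataset_manifest <- function(sample_ids, labels, scheme, split = "unassigned") {
  stopifnot(inherits(scheme, "class_scheme"))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop_cf("manifest sample ids must be unique", class = "cf_validation_error")
  if (is.character(labels) || is.factor(labels))
    labels <- scheme_index(scheme, labels)
  labels <- check_class_indices(labels, scheme$K, "manifest label")
  if (length(labels) != length(sample_ids))
    stop_cf("%d labels for %d sample ids", length(labels), length(sample_ids),
            class = "cf_validation_error")
  split <- rep_len(as.character(split), length(sample_ids))
  allowed <- c("unassigned", "test", "train", "validation")
  if (!all(split %in% allowed))
    stop_cf("split tags must be one of %s", paste(allowed, collapse = "/"),
            class = "cf_validation_error")
  df <- data.frame(sample_id = sample_ids, label = labels, split = split,
                   stringsAsFactors = FALSE)
  structure(df, scheme = scheme, class = c("dataset_manifest", "data.frame"))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  sc <- attr(x, "scheme")
  cat("Dataset manifest:", nrow(x), "entries\n")
  print(table(class = factor(sc$names[x$label], levels = sc$names),
              split = factor(x$split, levels = c("unassigned", "test", "train", "validation"))))
  invisible(x)
}

#' Per-class entry counts of a manifest
#'
#' @param manifest A \code{\link{dataset_manifest}}.
#' @return Named integer vector, one count per class in scheme order.
#' @export
class_counts <- function(manifest) {
  sc <- attr(manifest, "scheme")
  cnt <- tabulate(manifest$label, nbins = sc$K)
  names(cnt) <- sc$names
  cnt
}

#' Read a manifest from CSV
#'
#' Expected header: \code{sample_id,label,split} (split optional; missing
#' split column means all entries are "unassigned"). Labels in the file
#' are class names.
#'
#' @param path CSV path.
#' @param scheme A \code{\link{class_scheme}}.
#' @return A \code{\link{dataset_manifest}}.
#' @export
read_manifest <- function(path, scheme) {
  if (!file.exists(path))
    stop_cf("manifest not found: %s", path, class = "cf_io_error")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "label")
  if (!all(need %in% names(df)))
    stop_cf("manifest must have columns sample_id,label[,split]; found (%s)",
            paste(names(df), collapse = ","), class = "cf_format_error")
  split <- if ("split" %in% names(df)) df$split else "unassigned"
  dataset_manifest(df$sample_id, df$label, scheme, split = split)
}

#' Write a manifest to CSV
#'
#' @param manifest A \code{\link{dataset_manifest}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_manifest <- function(manifest, path) {
  sc <- attr(manifest, "scheme")
  out <- data.frame(sample_id = manifest$sample_id,
                    label = sc$names[manifest$label],
                    split = manifest$split, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Subset a manifest keeping class semantics.
manifest_subset <- function(manifest, idx, split = NULL) {
  sc <- attr(manifest, "scheme")
  dataset_manifest(manifest$sample_id[idx], manifest$label[idx], sc,
                   split = if (is.null(split)) manifest$split[idx] else split)
}
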