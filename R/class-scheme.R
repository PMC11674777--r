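#' Ordered class scheme
#'
#' A class scheme fixes the set and the *order* of the class labels. The
#' order is significant: severity stages are ordinal, files must list one
#' probability column per class in scheme order, and the ordinally weighted
#' agreement metrics depend on the distance between class positions.
#'
#' @param names Character vector of unique class labels, in increasing
#'   severity order.
#' @return An object of class \code{class_scheme} with elements
#'   \code{names} and \code{K} (number of classes).
#' @examples
#' class_scheme(c("none", "very_mild", "mild", "moderate"))
#' @export
class_scheme <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L)
    stop_cf("a class scheme needs at least 2 classes, got %d", length(names),
            class = "cf_scheme_error")
  if (anyDuplicated(names))
    stop_cf("class names must be unique; duplicated: %s",
            paste(unique(names[duplicated(names)]), collapse = ", "),
            class = "cf_scheme_error")
  structure(list(names = names, K = length(names)), class = "class_scheme")
}

#' The four OASIS-derived dementia severity classes
#'
#' Convenience constructor for the severity scheme used throughout the
#' examples: none < very_mild < mild < moderate.
#'
#' @return A \code{\link{class_scheme}} with K = 4.
#' @export
oasis_scheme <- function() {
  class_scheme(c("none", "very_mild", "mild", "moderate"))
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("Class scheme (", x$K, " ordered classes): ",
      paste(x$names, collapse = " < "), "\n", sep = "")
  invisible(x)
}

# Map class names to 1-based indices under a scheme, with validation.
scheme_index <- function(scheme, labels) {
  idx <- match(as.character(labels), scheme$names)
  if (anyNA(idx))
    stop_cf("unknown class label(s): %s",
            paste(unique(labels[is.na(idx)]), collapse = ", "),
            class = "cf_scheme_error")
  idx
}

check_class_indices <- function(idx, K, what = "class index") {
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > K))
    stop_cf("%s out of range [1, %d]", what, K, class = "cf_validation_error")
  idx
}
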