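# Class-imbalance protocol: (1) reserve a real-image test set per class
# BEFORE any resampling, (2) bring every remaining class to a common
# per-class target by undersampling majorities / duplicating minorities,
# (3) split the balanced pool into train and validation, stratified.

#' Per-class test-reservation rules
#'
#' Each class reserves either an absolute count or a fraction of its
#' entries. The reference protocol reserves 20% of the rarest (moderate)
#' class and 770 images from each of the other three.
#'
#' @param counts Named numeric vector of absolute counts per class name
#'   (may be a subset of classes).
#' @param fractions Named numeric vector of fractions in (0, 1).
#' @param rounding How fractional reservations are rounded: "half_up"
#'   (default), "floor" or "ceiling".
#' @return A \code{reservation_rules} object.
#' @export
reservation_rules <- function(counts = NULL, fractions = NULL,
                              rounding = c("half_up", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!is.null(counts)) {
    if (is.null(names(counts)) || any(counts < 0) || any(counts != floor(counts)))
      stop_cf("counts must be named non-negative integers", class = "cf_config_error")
  }
  if (!is.null(fractions)) {
    if (is.null(names(fractions)) || any(fractions <= 0) || any(fractions >= 1))
      stop_cf("fractions must be named values in (0, 1)", class = "cf_config_error")
  }
  overlap <- intersect(names(counts), names(fractions))
  if (length(overlap))
    stop_cf("class(es) given both a count and a fraction: %s",
            paste(overlap, collapse = ", "), class = "cf_config_error")
  structure(list(counts = counts, fractions = fractions, rounding = rounding),
            class = "reservation_rules")
}

apply_rounding <- function(x, mode) {
  switch(mode, half_up = round_half_up(x), floor = floor(x), ceiling = ceiling(x))
}

#' Reserve a per-class test set
#'
#' Samples the requested number (or rounded fraction) of entries of each
#' class uniformly without replacement into a test manifest; the
#' complement becomes the resampling pool. Classes with no rule reserve
#' nothing. Runs before any oversampling, so the test set contains only
#' original (never replicated) samples.
#'
#' @param manifest A \code{\link{dataset_manifest}}.
#' @param rules A \code{\link{reservation_rules}}.
#' @param seed Integer RNG seed.
#' @return List with \code{test} and \code{pool} manifests; disjoint,
#'   jointly exhaustive, split tags set to "test"/"unassigned".
#' @export
reserve_test_split <- function(manifest, rules, seed) {
  stopifnot(inherits(manifest, "dataset_manifest"),
            inherits(rules, "reservation_rules"))
  sc <- attr(manifest, "scheme")
  n_per <- class_counts(manifest)
  take <- stats::setNames(integer(sc$K), sc$names)
  for (cls in names(rules$counts)) {
    scheme_index(sc, cls)
    take[cls] <- as.integer(rules$counts[[cls]])
  }
  for (cls in names(rules$fractions)) {
    scheme_index(sc, cls)
    take[cls] <- as.integer(apply_rounding(rules$fractions[[cls]] * n_per[cls],
                                           rules$rounding))
  }
  short <- which(take > n_per)
  if (length(short))
    stop_cf("reservation for class '%s' (%d) exceeds its size (%d)",
            sc$names[short[1L]], take[short[1L]], n_per[short[1L]],
            class = "cf_infeasible_error")
  test_idx <- integer(0)
  with_seed(seed, {
    for (k in seq_len(sc$K)) {
      if (take[k] == 0L) next
      members <- which(manifest$label == k)
      test_idx <- c(test_idx, sort(sample(members, take[k])))
    }
  })
  pool_idx <- setdiff(seq_len(nrow(manifest)), test_idx)
  list(test = manifest_subset(manifest, test_idx, split = "test"),
       pool = manifest_subset(manifest, pool_idx, split = "unassigned"))
}

#' Rebalance a pool to a fixed per-class size
#'
#' Classes above the target are subsampled uniformly without replacement;
#' classes below keep every original entry once and add duplicates drawn
#' with replacement until the target is reached. Duplicate entries get
#' replica ids \code{<original_id>#r<k>} (k counting duplicates of that
#' original), so downstream leakage checks can recognize them.
#'
#' Oversampling is plain duplication: for medical scans, synthetic or
#' geometric augmentation risks destroying diagnostic structure, so
#' duplication is the conservative choice.
#'
#' @param pool A \code{\link{dataset_manifest}} (every class non-empty).
#' @param target Positive integer: entries per class after balancing.
#' @param seed Integer RNG seed.
#' @return A balanced \code{\link{dataset_manifest}} with exactly
#'   \code{target} entries per class.
#' @export
rebalance <- function(pool, target, seed) {
  stopifnot(inherits(pool, "dataset_manifest"))
  target <- as.integer(target)
  if (target < 1L) stop_cf("target must be >= 1", class = "cf_config_error")
  sc <- attr(pool, "scheme")
  n_per <- class_counts(pool)
  if (any(n_per == 0L))
    stop_cf("class '%s' is empty; cannot oversample from nothing",
            sc$names[which(n_per == 0L)[1L]], class = "cf_infeasible_error")
  ids <- character(0); labs <- integer(0)
  with_seed(seed, {
    for (k in seq_len(sc$K)) {
      members <- which(pool$label == k)
      if (length(members) >= target) {
        keep <- sort(sample(members, target))
        ids <- c(ids, pool$sample_id[keep])
      } else {
        extra <- sample(members, target - length(members), replace = TRUE)
        rep_counter <- stats::setNames(integer(length(members)),
                                       pool$sample_id[members])
        replica_ids <- character(length(extra))
        for (i in seq_along(extra)) {
          oid <- pool$sample_id[extra[i]]
          rep_counter[oid] <- rep_counter[oid] + 1L
          replica_ids[i] <- sprintf("%s#r%d", oid, rep_counter[oid])
        }
        ids <- c(ids, pool$sample_id[members], replica_ids)
      }
      labs <- c(labs, rep(k, target))
    }
  })
  dataset_manifest(ids, labs, sc, split = "unassigned")
}

#' Stratified train/validation split
#'
#' Partitions a manifest into train and validation sets of the requested
#' total sizes, allocating within each class proportionally to its size
#' (largest-remainder rounding, so totals are met exactly). On a
#' balanced manifest this yields equal per-class counts — e.g. a
#' 24,000-entry manifest split 19,000/5,000 contributes 4,750 train and
#' 1,250 validation entries per class.
#'
#' @param balanced A \code{\link{dataset_manifest}}.
#' @param train_count,val_count Entry totals; must sum to
#'   \code{nrow(balanced)}.
#' @param seed Integer RNG seed.
#' @return List with \code{train} and \code{validation} manifests,
#'   disjoint and jointly exhaustive, split tags set accordingly.
#' @export
stratified_split <- function(balanced, train_count, val_count, seed) {
  stopifnot(inherits(balanced, "dataset_manifest"))
  train_count <- as.integer(train_count); val_count <- as.integer(val_count)
  n <- nrow(balanced)
  if (train_count < 0L || val_count < 0L || train_count + val_count != n)
    stop_cf("train (%d) + validation (%d) must equal the manifest size (%d)",
            train_count, val_count, n, class = "cf_validation_error")
  sc <- attr(balanced, "scheme")
  n_per <- class_counts(balanced)
  # largest-remainder allocation of train_count across classes
  quota <- train_count * n_per / n
  alloc <- floor(quota)
  shortfall <- train_count - sum(alloc)
  if (shortfall > 0L) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(shortfall)]
    alloc[extra] <- alloc[extra] + 1L
  }
  train_idx <- integer(0)
  with_seed(seed, {
    for (k in seq_len(sc$K)) {
      members <- which(balanced$label == k)
      if (alloc[k] > length(members))
        stop_cf("cannot allocate %d train entries to class '%s' of size %d",
                alloc[k], sc$names[k], length(members), class = "cf_validation_error")
      if (alloc[k] > 0L)
        train_idx <- c(train_idx, sort(sample(members, alloc[k])))
    }
  })
  val_idx <- setdiff(seq_len(n), train_idx)
  list(train = manifest_subset(balanced, train_idx, split = "train"),
       validation = manifest_subset(balanced, val_idx, split = "validation"))
}
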