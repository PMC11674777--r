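# Synthetic-data generators: label manifests with prescribed class
# counts and probabilistic classifier outputs of controllable skill,
# sharpness and inter-model error correlation. These stand in for
# trained-network outputs so fusion, metrics, search and balancing are
# testable end to end without any image data.

#' Specification of one simulated classifier
#'
#' \code{skill} is the probability that the model's modal (top-scoring)
#' class equals the true class. \code{concentration} controls how sharply
#' the emitted probability row peaks on the modal class (Dirichlet
#' concentration of the modal component; higher is nearer one-hot — the
#' default 20 is sharp but leaves ROC-AUC informative rather than
#' saturated). With \code{adjacent_bias} on (the default), wrong modal
#' classes prefer stages adjacent to the truth, mirroring how real
#' stage-classifier errors concentrate between neighboring severities.
#'
#' @param skill Probability in [0, 1] that the modal class is correct.
#' @param concentration Positive sharpness of emitted rows.
#' @param adjacent_bias If TRUE, error classes are drawn with weight
#'   halving per step of ordinal distance; if FALSE, uniformly.
#' @return A \code{sim_model_spec} object.
#' @export
sim_model_spec <- function(skill, concentration = 20, adjacent_bias = TRUE) {
  if (skill < 0 || skill > 1)
    stop_cf("skill must lie in [0, 1]", class = "cf_config_error")
  if (concentration <= 0)
    stop_cf("concentration must be positive", class = "cf_config_error")
  structure(list(skill = skill, concentration = concentration,
                 adjacent_bias = isTRUE(adjacent_bias)),
            class = "sim_model_spec")
}

#' Generate a label manifest with prescribed class counts
#'
#' Produces a shuffled manifest with exactly the requested number of
#' entries per class and synthetic sample ids, e.g. the full OASIS-style
#' severity histogram 67,222 / 13,725 / 5,002 / 488.
#'
#' @param counts Integer vector of per-class counts, one per scheme
#'   class, at least two positive.
#' @param scheme A \code{\link{class_scheme}}.
#' @param seed Integer RNG seed.
#' @return A \code{\link{dataset_manifest}} with \code{sum(counts)}
#'   entries in shuffled order.
#' @export
generate_manifest <- function(counts, scheme, seed) {
  stopifnot(inherits(scheme, "class_scheme"))
  counts <- as.integer(counts)
  if (length(counts) != scheme$K)
    stop_cf("%d counts for %d classes", length(counts), scheme$K,
            class = "cf_validation_error")
  if (any(counts < 0L) || sum(counts > 0L) < 2L)
    stop_cf("need non-negative counts with at least two non-empty classes",
            class = "cf_validation_error")
  labels <- rep(seq_len(scheme$K), counts)
  n <- length(labels)
  with_seed(seed, {
    labels <- sample(labels)
  })
  ids <- sprintf("s%0*d", max(6L, nchar(n)), seq_len(n))
  dataset_manifest(ids, labels, scheme)
}

# Draw a probability row peaked on `modal`: Dirichlet with concentration
# on the modal component, then (if needed) swap the max into the modal
# slot so the argmax is the modal class by construction.
draw_row <- function(modal, K, concentration) {
  alpha <- rep(1, K)
  alpha[modal] <- concentration
  g <- stats::rgamma(K, shape = alpha)
  row <- g / sum(g)
  top <- which.max(row)
  if (top != modal) {
    tmp <- row[modal]; row[modal] <- row[top]; row[top] <- tmp
  }
  row
}

# Pick a wrong modal class for a sample with true class `truth`.
draw_error_class <- function(truth, K, adjacent_bias) {
  wrong <- setdiff(seq_len(K), truth)
  if (length(wrong) == 1L) return(wrong)
  w <- if (adjacent_bias) 2^-(abs(wrong - truth) - 1) else rep(1, length(wrong))
  wrong[sample.int(length(wrong), 1L, prob = w)]
}

# Core generator given a precomputed error indicator per sample.
emit_predictions <- function(labels, err, spec, K, model_id, sample_ids, scheme) {
  n <- length(labels)
  probs <- matrix(0, n, K)
  for (i in seq_len(n)) {
    modal <- if (err[i]) draw_error_class(labels[i], K, spec$adjacent_bias)
             else labels[i]
    probs[i, ] <- draw_row(modal, K, spec$concentration)
  }
  prediction_set(model_id, sample_ids, probs, scheme, truth = labels)
}

#' Simulate one model's probabilistic predictions
#'
#' For each sample, the modal class equals the truth with probability
#' \code{spec$skill}; otherwise a wrong class is drawn (adjacent-biased
#' if configured). The emitted row is a Dirichlet draw concentrated on
#' the modal class, constructed so its argmax IS the modal class — hence
#' empirical argmax accuracy is an unbiased estimator of skill.
#'
#' @param manifest A \code{\link{dataset_manifest}} supplying truth
#'   labels and sample ids.
#' @param spec A \code{\link{sim_model_spec}}.
#' @param seed Integer RNG seed.
#' @param model_id Identifier for the emitted set.
#' @return A validated \code{\link{prediction_set}} with truth attached.
#' @export
simulate_model_predictions <- function(manifest, spec, seed,
                                       model_id = "sim_model") {
  stopifnot(inherits(manifest, "dataset_manifest"),
            inherits(spec, "sim_model_spec"))
  sc <- attr(manifest, "scheme")
  with_seed(seed, {
    err <- stats::runif(nrow(manifest)) >= spec$skill
    emit_predictions(manifest$label, err, spec, sc$K, model_id,
                     manifest$sample_id, sc)
  })
}

#' Simulate a correlated pair of models
#'
#' Both models score the same samples; their error events are coupled
#' through a shared "hard case" mechanism: with probability \code{rho} a
#' sample presents the SAME latent difficulty draw to both models, with
#' probability \code{1 - rho} each model gets an independent draw. A
#' model errs when its difficulty draw exceeds its skill. Hence
#' \code{rho = 1} with equal skills makes the two error sets identical,
#' and \code{rho = 0} makes errors independent (joint error rate =
#' product of the individual rates); model-vs-model agreement rises
#' monotonically with \code{rho}.
#'
#' @param manifest A \code{\link{dataset_manifest}}.
#' @param spec_a,spec_b \code{\link{sim_model_spec}}s for the two models.
#' @param rho Error-event correlation in [0, 1].
#' @param seed Integer RNG seed.
#' @param model_ids Character vector of two model identifiers.
#' @return List of two aligned \code{\link{prediction_set}}s.
#' @export
simulate_correlated_pair <- function(manifest, spec_a, spec_b, rho, seed,
                                     model_ids = c("model_a", "model_b")) {
  stopifnot(inherits(manifest, "dataset_manifest"),
            inherits(spec_a, "sim_model_spec"),
            inherits(spec_b, "sim_model_spec"))
  if (rho < 0 || rho > 1)
    stop_cf("rho must lie in [0, 1]", class = "cf_config_error")
  sc <- attr(manifest, "scheme")
  n <- nrow(manifest)
  with_seed(seed, {
    u_shared <- stats::runif(n)
    u_a <- stats::runif(n)
    u_b <- stats::runif(n)
    use_shared <- stats::runif(n) < rho
    d_a <- ifelse(use_shared, u_shared, u_a)
    d_b <- ifelse(use_shared, u_shared, u_b)
    err_a <- d_a >= spec_a$skill
    err_b <- d_b >= spec_b$skill
    a <- emit_predictions(manifest$label, err_a, spec_a, sc$K, model_ids[1L],
                          manifest$sample_id, sc)
    b <- emit_predictions(manifest$label, err_b, spec_b, sc$K, model_ids[2L],
                          manifest$sample_id, sc)
    list(a, b)
  })
}
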