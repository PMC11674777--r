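# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive quantities by the most literal route available
# (exhaustive pair comparison, hand-rolled formulas, double loops) so they
# share no code with the package implementations they check.

scheme4 <- cuckoofuse::oasis_scheme()
scheme2 <- cuckoofuse::class_scheme(c("neg", "pos"))

# Random valid prediction-set fixture (rows normalized uniforms).
random_pset <- function(n, scheme, model_id = "m", with_truth = TRUE,
                        ids = sprintf("s%03d", seq_len(n))) {
  p <- matrix(stats::runif(n * scheme$K), n, scheme$K)
  p <- p / rowSums(p)
  truth <- if (with_truth) sample.int(scheme$K, n, replace = TRUE) else NULL
  cuckoofuse::prediction_set(model_id, ids, p, scheme, truth = truth)
}

# Aligned pair sharing ids and truth.
random_pset_pair <- function(n, scheme) {
  ids <- sprintf("s%03d", seq_len(n))
  truth <- sample.int(scheme$K, n, replace = TRUE)
  mk <- function(mid) {
    p <- matrix(stats::runif(n * scheme$K), n, scheme$K)
    p <- p / rowSums(p)
    cuckoofuse::prediction_set(mid, ids, p, scheme, truth = truth)
  }
  list(mk("a"), mk("b"))
}

# Exhaustive pairwise-comparison AUC: P(positive outscores negative),
# ties counted one half.
auc_pairwise_oracle <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}

micro_auc_oracle <- function(truth, probs) {
  K <- ncol(probs)
  onehot <- matrix(FALSE, nrow(probs), K)
  onehot[cbind(seq_len(nrow(probs)), truth)] <- TRUE
  auc_pairwise_oracle(as.vector(probs), as.vector(onehot))
}

# Cohen's kappa, coded independently: chance agreement from the two
# raters' SEPARATE marginals.
cohen_kappa_oracle <- function(a, b, K) {
  n <- length(a)
  po <- mean(a == b)
  pa <- tabulate(a, K) / n
  pb <- tabulate(b, K) / n
  pe <- sum(pa * pb)
  (po - pe) / (1 - pe)
}

# Literal two-model grid search: best accuracy over a uniform weight
# grid, fused and decided with independent code (which.max, double loop).
grid_search_oracle <- function(probs_a, probs_b, truth, pitch = 0.01) {
  g <- seq(0, 1, by = pitch)
  best <- -Inf
  for (w1 in g) for (w2 in g) {
    if (w1 == 0 && w2 == 0) next
    fused <- w1 * probs_a + w2 * probs_b
    labels <- apply(fused, 1L, which.max)
    acc <- mean(labels == truth)
    if (acc > best) best <- acc
  }
  best
}

# Pure random search at a fixed evaluation budget (baseline for the
# budget-dominance check).
random_search_baseline <- function(fitness, dim, budget) {
  best <- -Inf
  for (i in seq_len(budget)) {
    w <- stats::runif(dim)
    if (all(w == 0)) next
    f <- fitness(w)
    if (f > best) best <- f
  }
  best
}

# Two-model synthetic problem for optimizer checks.
make_two_model_problem <- function(seed, n = 300L, skill_a = 0.95,
                                   skill_b = 0.55, rho = 0.3) {
  counts <- c(n %/% 2, n %/% 4, n %/% 8, n - n %/% 2 - n %/% 4 - n %/% 8)
  man <- cuckoofuse::generate_manifest(counts, scheme4, seed = seed)
  cuckoofuse::simulate_correlated_pair(
    man,
    cuckoofuse::sim_model_spec(skill_a),
    cuckoofuse::sim_model_spec(skill_b),
    rho = rho, seed = seed + 1000L)
}
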