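# Cuckoo Search over fusion weight vectors. Candidate solutions ("eggs"
# in "nests") are perturbed by Levy flights (Mantegna construction); the
# fitter of a proposal and a randomly chosen nest survives, a fraction pa
# of the worst nests is abandoned and re-drawn each generation, and the
# best solutions are archived. The search box is [0,1]^M with no simplex
# constraint: only the argmax of the weighted sum matters downstream, and
# reported well-performing weight pairs need not sum to one.

#' Cuckoo Search configuration
#'
#' Defaults are standard small-population Cuckoo Search settings sized to
#' low-dimensional weight search: 25 nests, abandon fraction 0.25, Levy
#' exponent 1.5, step scale 0.05 (in weight units), up to 200 generations
#' with early stop after 10 consecutive generations improving by less
#' than 1e-6.
#'
#' @param n_nests Population size (>= 2).
#' @param pa Fraction of worst nests abandoned and re-drawn per
#'   generation, in [0, 1).
#' @param levy_beta Levy stability exponent in (0, 2].
#' @param step_scale Positive step-size multiplier alpha0.
#' @param bounds Two-column matrix (lo, hi) per searched dimension, or
#'   NULL for [0, 1] everywhere.
#' @param max_generations Generation budget (>= 0).
#' @param tol Improvement threshold counting as progress.
#' @param patience Consecutive sub-tol generations before stopping.
#' @param seed Integer RNG seed; the whole search is reproducible from it.
#' @param archive_size Number of top weight vectors retained.
#' @return A \code{cs_config} object.
#' @export
cs_config <- function(n_nests = 25L, pa = 0.25, levy_beta = 1.5,
                      step_scale = 0.05, bounds = NULL,
                      max_generations = 200L, tol = 1e-6, patience = 10L,
                      seed = 1L, archive_size = 10L) {
  if (n_nests < 2L) stop_cf("n_nests must be >= 2", class = "cf_config_error")
  if (pa < 0 || pa >= 1) stop_cf("pa must lie in [0, 1)", class = "cf_config_error")
  if (levy_beta <= 0 || levy_beta > 2)
    stop_cf("levy_beta must lie in (0, 2]", class = "cf_config_error")
  if (step_scale <= 0) stop_cf("step_scale must be positive", class = "cf_config_error")
  if (max_generations < 0L) stop_cf("max_generations must be >= 0", class = "cf_config_error")
  if (tol < 0) stop_cf("tol must be non-negative", class = "cf_config_error")
  if (patience < 1L) stop_cf("patience must be >= 1", class = "cf_config_error")
  if (archive_size < 1L) stop_cf("archive_size must be >= 1", class = "cf_config_error")
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 2L || any(bounds[, 1L] >= bounds[, 2L]) ||
        any(bounds < 0) || any(bounds > 1))
      stop_cf("bounds must be well-ordered [lo, hi] pairs within [0, 1]",
              class = "cf_config_error")
  }
  structure(list(n_nests = as.integer(n_nests), pa = pa, levy_beta = levy_beta,
                 step_scale = step_scale, bounds = bounds,
                 max_generations = as.integer(max_generations), tol = tol,
                 patience = as.integer(patience), seed = as.integer(seed),
                 archive_size = as.integer(archive_size)),
            class = "cs_config")
}

# sigma_u of the Mantegna construction for a given stability exponent.
levy_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' One Levy-flight step vector
#'
#' Mantegna construction: each component is u / |v|^(1/beta) with
#' u ~ N(0, sigma_u(beta)^2) and v ~ N(0, 1), giving a heavy-tailed,
#' symmetric step distribution that mixes many small moves with
#' occasional large jumps. Uses the current RNG state; seed via the
#' caller (e.g. \code{cs_config$seed} inside \code{\link{cs_optimize}}).
#'
#' @param beta Stability exponent in (0, 2].
#' @param dim Number of components (>= 1).
#' @return Numeric vector of length \code{dim}.
#' @export
levy_step <- function(beta, dim) {
  if (beta <= 0 || beta > 2)
    stop_cf("levy beta must lie in (0, 2]", class = "cf_config_error")
  if (dim < 1L) stop_cf("dim must be >= 1", class = "cf_config_error")
  u <- stats::rnorm(dim, sd = levy_sigma(beta))
  v <- stats::rnorm(dim)
  u / abs(v)^(1 / beta)
}

cs_bounds <- function(cfg, dim) {
  if (is.null(cfg$bounds)) cbind(lo = rep(0, dim), hi = rep(1, dim))
  else if (nrow(cfg$bounds) == dim) cfg$bounds
  else stop_cf("bounds have %d rows for %d dimensions", nrow(cfg$bounds), dim,
               class = "cf_config_error")
}

#' Initialize the nest population
#'
#' Draws \code{n_nests} weight vectors uniformly within the configured
#' per-dimension bounds; fitness is left unevaluated. Uses the current
#' RNG state.
#'
#' @param cfg A \code{\link{cs_config}}.
#' @param dim Number of weights searched (>= 2 for fusion problems).
#' @return Numeric n_nests x dim matrix of candidate weight vectors.
#' @export
init_nests <- function(cfg, dim) {
  b <- cs_bounds(cfg, dim)
  nests <- matrix(stats::runif(cfg$n_nests * dim), cfg$n_nests, dim)
  sweep(sweep(nests, 2L, b[, 2L] - b[, 1L], "*"), 2L, b[, 1L], "+")
}

#' Accuracy fitness for fusion-weight search
#'
#' Returns the deterministic objective w -> accuracy of the argmax labels
#' of the weighted fusion against the shared truth: the paper-style
#' fitness evaluated on a validation prediction set.
#'
#' @param models List of aligned \code{\link{prediction_set}}s, each
#'   carrying truth.
#' @return Function mapping a weight vector to accuracy in [0, 1].
#' @export
make_accuracy_fitness <- function(models) {
  truth <- assert_aligned(models)
  if (is.null(truth))
    stop_cf("accuracy fitness requires truth labels on the prediction sets",
            class = "cf_validation_error")
  arrs <- lapply(models, function(m) m$probs)
  force(truth)
  function(w) {
    w <- check_weights(w, n_models = length(arrs))
    probs <- w[1L] * arrs[[1L]]
    for (m in seq_along(arrs)[-1L]) probs <- probs + w[m] * arrs[[m]]
    mean(max.col(probs, ties.method = "first") == truth)
  }
}

#' Scott's Pi fitness for fusion-weight search
#'
#' Objective w -> Scott's Pi between the truth and the fused argmax
#' labels. An undefined pi (both streams degenerate on one class) maps
#' to -1 so the optimizer treats degeneracy as the worst outcome rather
#' than failing.
#'
#' @param models List of aligned \code{\link{prediction_set}}s with truth.
#' @param weighting Scott's Pi weighting ("none", "linear", "quadratic").
#' @return Function mapping a weight vector to pi (or -1 when undefined).
#' @export
make_agreement_fitness <- function(models, weighting = "none") {
  truth <- assert_aligned(models)
  if (is.null(truth))
    stop_cf("agreement fitness requires truth labels on the prediction sets",
            class = "cf_validation_error")
  arrs <- lapply(models, function(m) m$probs)
  K <- models[[1L]]$scheme$K
  function(w) {
    w <- check_weights(w, n_models = length(arrs))
    probs <- w[1L] * arrs[[1L]]
    for (m in seq_along(arrs)[-1L]) probs <- probs + w[m] * arrs[[m]]
    r <- scotts_pi(truth, max.col(probs, ties.method = "first"), K, weighting)
    if (r$defined) r$pi else -1
  }
}

# Deterministic candidate ordering: fitness desc, then smaller Euclidean
# norm, then lexicographic — fixes archive order under fitness ties.
cs_order <- function(fitness, weights) {
  ord <- order(-fitness, rowSums(weights^2))
  # refine lexicographically within remaining ties
  key <- apply(weights, 1L, function(w) paste(sprintf("%.17g", w), collapse = ","))
  ord[order(-fitness[ord], rowSums(weights[ord, , drop = FALSE]^2), key[ord])]
}

#' Optimize fusion weights by Cuckoo Search
#'
#' Per generation: (i) each nest proposes
#' \code{x' = x + step_scale * levy_step * (x - x_best)} component-wise
#' (a nest sitting exactly at the incumbent best takes a pure Levy step
#' of magnitude \code{step_scale}), clipped to bounds; the proposal
#' replaces a randomly chosen nest if fitter. (ii) The worst
#' \code{ceiling(pa * n_nests)} nests are abandoned and re-drawn
#' uniformly in bounds. (iii) The best-so-far solution and the archive
#' are updated. Stops at \code{max_generations} or once the
#' best-fitness improvement stays below \code{tol} for \code{patience}
#' consecutive generations. The best-so-far is tracked outside the
#' population, so the fitness history is non-decreasing, and the whole
#' run is reproducible from \code{cfg$seed}.
#'
#' @param fitness Deterministic objective mapping a weight vector to a
#'   finite scalar (larger is better).
#' @param dim Number of weights searched.
#' @param cfg A \code{\link{cs_config}}.
#' @return A \code{cs_result}: list with \code{best_weights},
#'   \code{best_fitness}, \code{history} (per-generation best, index 1 =
#'   initial population), \code{archive} (data frame of top vectors),
#'   \code{evaluations}, \code{generations}, \code{seed}, \code{config}.
#' @export
cs_optimize <- function(fitness, dim, cfg = cs_config()) {
  stopifnot(is.function(fitness), dim >= 1L, inherits(cfg, "cs_config"))
  b <- cs_bounds(cfg, dim)
  evals <- 0L
  eval_fit <- function(w) {
    evals <<- evals + 1L
    f <- fitness(w)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
      stop_cf("fitness returned a non-finite value at weights (%s)",
              paste(sprintf("%.6g", w), collapse = ", "),
              class = "cf_optimization_error")
    f
  }
  clip <- function(w) pmin(pmax(w, b[, 1L]), b[, 2L])

  with_seed(cfg$seed, {
    nests <- init_nests(cfg, dim)
    fit <- apply(nests, 1L, eval_fit)

    # archive of distinct top candidates
    arch_w <- nests
    arch_f <- fit
    prune_archive <- function() {
      key <- apply(arch_w, 1L, function(w) paste(sprintf("%.17g", w), collapse = ","))
      keep <- !duplicated(key)
      arch_w <<- arch_w[keep, , drop = FALSE]
      arch_f <<- arch_f[keep]
      ord <- cs_order(arch_f, arch_w)
      ord <- utils::head(ord, cfg$archive_size)
      arch_w <<- arch_w[ord, , drop = FALSE]
      arch_f <<- arch_f[ord]
    }
    add_to_archive <- function(w, f) {
      arch_w <<- rbind(arch_w, w)
      arch_f <<- c(arch_f, f)
    }
    prune_archive()

    best_i <- cs_order(fit, nests)[1L]
    best_w <- nests[best_i, ]
    best_f <- fit[best_i]
    history <- best_f
    stalled <- 0L
    gen <- 0L

    while (gen < cfg$max_generations) {
      gen <- gen + 1L
      # (i) egg laying: Levy proposals against random nests
      for (i in seq_len(cfg$n_nests)) {
        diff <- nests[i, ] - best_w
        step <- if (all(diff == 0)) cfg$step_scale * levy_step(cfg$levy_beta, dim)
                else cfg$step_scale * levy_step(cfg$levy_beta, dim) * diff
        prop <- clip(nests[i, ] + step)
        # the all-zero corner of the box is not a valid weight vector
        # (no model would contribute); discard such proposals
        if (all(prop == 0)) next
        f_prop <- eval_fit(prop)
        j <- sample.int(cfg$n_nests, 1L)
        if (f_prop > fit[j]) {
          nests[j, ] <- prop
          fit[j] <- f_prop
          add_to_archive(prop, f_prop)
        }
      }
      # (ii) abandon the worst pa fraction, re-draw uniformly
      n_abandon <- ceiling(cfg$pa * cfg$n_nests)
      if (n_abandon > 0L) {
        worst <- utils::tail(cs_order(fit, nests), n_abandon)
        fresh <- matrix(stats::runif(n_abandon * dim), n_abandon, dim)
        fresh <- sweep(sweep(fresh, 2L, b[, 2L] - b[, 1L], "*"), 2L, b[, 1L], "+")
        nests[worst, ] <- fresh
        fit[worst] <- apply(fresh, 1L, eval_fit)
        for (r in seq_len(n_abandon)) add_to_archive(fresh[r, ], fit[worst[r]])
      }
      # (iii) update best-so-far and archive
      gen_best <- cs_order(fit, nests)[1L]
      if (fit[gen_best] > best_f) {
        improvement <- fit[gen_best] - best_f
        best_f <- fit[gen_best]
        best_w <- nests[gen_best, ]
      } else improvement <- 0
      prune_archive()
      history <- c(history, best_f)
      stalled <- if (improvement < cfg$tol) stalled + 1L else 0L
      if (stalled >= cfg$patience) break
    }

    archive <- data.frame(arch_w)
    names(archive) <- paste0("w", seq_len(dim))
    archive$fitness <- arch_f
    structure(list(best_weights = unname(best_w), best_fitness = best_f,
                   history = history, archive = archive,
                   evaluations = evals, generations = gen,
                   seed = cfg$seed, config = cfg),
              class = "cs_result")
  })
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("Cuckoo Search: best fitness %.6f at weights (%s) after %d generations, %d evaluations (seed %d)\n",
              x$best_fitness, paste(sprintf("%.4f", x$best_weights), collapse = ", "),
              x$generations, x$evaluations, x$seed))
  invisible(x)
}

#' Snap a weight vector to a grid
#'
#' Reports the nearest point of a uniform weight grid (default pitch
#' 0.05), for comparing a continuous search optimum against coarse
#' manual weight sweeps.
#'
#' @param w Weight vector.
#' @param pitch Grid pitch in weight units.
#' @return Snapped weight vector.
#' @export
snap_to_grid <- function(w, pitch = 0.05) {
  round_half_up(w / pitch) * pitch
}

#' Exhaustive fitness sweep over a two-model weight grid
#'
#' Evaluates the objective at every pair of a uniform grid over
#' [0,1] x [0,1] — the manual-sweep analogue against which the optimizer
#' is compared.
#'
#' @param fitness Objective as in \code{\link{cs_optimize}}.
#' @param pitch Grid pitch (default 0.05).
#' @return Data frame (w1, w2, fitness), one row per grid point with at
#'   least one positive weight.
#' @export
weight_sweep <- function(fitness, pitch = 0.05) {
  g <- seq(0, 1, by = pitch)
  grid <- expand.grid(w1 = g, w2 = g)
  grid <- grid[grid$w1 > 0 | grid$w2 > 0, ]
  grid$fitness <- vapply(seq_len(nrow(grid)),
                         function(i) fitness(c(grid$w1[i], grid$w2[i])),
                         numeric(1L))
  rownames(grid) <- NULL
  grid
}

#' Serialize a search result to JSON (+ history CSV)
#'
#' @param result A \code{cs_result}.
#' @param path Output JSON path; the per-generation history is written to
#'   \code{paste0(path, ".history.csv")}.
#' @return Invisibly, \code{path}.
#' @export
write_search_result <- function(result, path) {
  stopifnot(inherits(result, "cs_result"))
  cfg <- result$config
  jsonlite::write_json(
    list(best_weights = result$best_weights,
         best_fitness = result$best_fitness,
         archive = result$archive,
         evaluations = result$evaluations,
         generations = result$generations,
         seed = result$seed,
         config = cfg[setdiff(names(cfg), "bounds")]),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(generation = seq_along(result$history) - 1L,
                              best_fitness = result$history),
                   paste0(path, ".history.csv"), row.names = FALSE)
  invisible(path)
}
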