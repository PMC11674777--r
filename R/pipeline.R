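# End-to-end orchestration: simulate -> reserve/balance/split -> fuse ->
# optimize -> evaluate, driven by one config (YAML file or list) with a
# single top-level seed from which every stage derives its own.

default_config <- function() {
  list(
    classes = c("none", "very_mild", "mild", "moderate"),
    class_counts = c(67222L, 13725L, 5002L, 488L),
    reservation = list(fractions = c(moderate = 0.2),
                       counts = c(none = 770, very_mild = 770, mild = 770),
                       rounding = "half_up"),
    balance_target = 6000L,
    train_count = 19000L,
    val_count = 5000L,
    simulation = list(
      n_eval = 2000L,
      model_a = list(skill = 0.95, concentration = 20, adjacent_bias = TRUE),
      model_b = list(skill = 0.85, concentration = 20, adjacent_bias = TRUE),
      rho = 0.5),
    search = list(fitness = "accuracy", weighting = "none",
                  n_nests = 25L, pa = 0.25, levy_beta = 1.5,
                  step_scale = 0.05, max_generations = 200L,
                  tol = 1e-6, patience = 10L, archive_size = 10L),
    seed = 1L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML configuration and fills unspecified fields from the
#' package defaults (the OASIS-style severity scheme, printed class
#' counts, the 770-per-class / 20%-moderate reservation, 6000-per-class
#' balancing, 19,000/5,000 split, and standard search settings). Field
#' values are validated with errors naming the offending field.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides Optional named list merged over the file values.
#' @return A validated \code{run_config} list.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_cf("config file not found: %s", path, class = "cf_io_error")
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  check_field <- function(ok, field, msg) {
    if (!ok) stop_cf("config field '%s': %s", field, msg,
                     class = "cf_config_error")
  }
  check_field(length(cfg$classes) >= 2L, "classes", "need at least 2 class names")
  check_field(length(cfg$class_counts) == length(cfg$classes),
              "class_counts", "one count per class required")
  check_field(cfg$balance_target >= 1, "balance_target", "must be >= 1")
  check_field(cfg$train_count >= 0 && cfg$val_count >= 0,
              "train_count/val_count", "must be non-negative")
  check_field(cfg$search$fitness %in% c("accuracy", "scotts-pi"),
              "search.fitness", "must be 'accuracy' or 'scotts-pi'")
  check_field(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
              "seed", "must be a single integer")
  structure(cfg, class = "run_config")
}

#' Run the full synthetic workflow
#'
#' Executes the whole pipeline from one seed: (1) generate a manifest
#' with the configured class counts; (2) reserve the test set, rebalance
#' the pool to the per-class target, and split train/validation; (3)
#' simulate a correlated pair of models on an evaluation subset of the
#' validation set; (4) fuse by simple averaging and by Cuckoo-Search
#' optimized weights; (5) evaluate single models, the average ensemble
#' and the optimized ensemble with the full metric suite, plus the
#' pairwise agreement matrix.
#'
#' @param config A \code{run_config} from \code{\link{load_run_config}},
#'   or NULL for defaults.
#' @param quiet If FALSE, progress is logged to standard error.
#' @return List with manifests (\code{test}, \code{train},
#'   \code{validation}, \code{balanced}), the simulated \code{models},
#'   \code{agreement} matrix, \code{search} result, \code{fused_average}
#'   and \code{fused_optimized} predictions, and \code{reports} (named
#'   list of \code{metrics_report}s).
#' @export
run_pipeline <- function(config = NULL, quiet = TRUE) {
  cfg <- if (is.null(config)) load_run_config() else config
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  say <- function(...) if (!quiet) message(sprintf(...))
  scheme <- class_scheme(cfg$classes)

  say("generating manifest (%s entries)", format(sum(cfg$class_counts), big.mark = ","))
  manifest <- generate_manifest(cfg$class_counts, scheme,
                                seed = derive_seed(cfg$seed, 1L))

  rules <- reservation_rules(counts = cfg$reservation$counts,
                             fractions = cfg$reservation$fractions,
                             rounding = cfg$reservation$rounding)
  res <- reserve_test_split(manifest, rules, seed = derive_seed(cfg$seed, 2L))
  balanced <- rebalance(res$pool, cfg$balance_target,
                        seed = derive_seed(cfg$seed, 3L))
  split <- stratified_split(balanced, cfg$train_count, cfg$val_count,
                            seed = derive_seed(cfg$seed, 4L))
  say("reserved %d test, balanced to %d, split %d/%d",
      nrow(res$test), nrow(balanced), nrow(split$train), nrow(split$validation))

  # evaluation subset of the validation manifest (replicas resolve to the
  # same latent sample; for simulation each row is scored independently)
  n_eval <- min(cfg$simulation$n_eval, nrow(split$validation))
  eval_manifest <- with_seed(derive_seed(cfg$seed, 5L), {
    keep <- sort(sample.int(nrow(split$validation), n_eval))
    manifest_subset(split$validation, keep)
  })

  sa <- do.call(sim_model_spec, cfg$simulation$model_a)
  sb <- do.call(sim_model_spec, cfg$simulation$model_b)
  models <- simulate_correlated_pair(eval_manifest, sa, sb,
                                     rho = cfg$simulation$rho,
                                     seed = derive_seed(cfg$seed, 6L))
  say("simulated models '%s' and '%s' on %d samples",
      models[[1L]]$model_id, models[[2L]]$model_id, n_eval)

  agreement <- agreement_matrix(models, weighting = cfg$search$weighting)

  fitness <- if (cfg$search$fitness == "accuracy") make_accuracy_fitness(models)
             else make_agreement_fitness(models, cfg$search$weighting)
  cs_cfg <- cs_config(n_nests = cfg$search$n_nests, pa = cfg$search$pa,
                      levy_beta = cfg$search$levy_beta,
                      step_scale = cfg$search$step_scale,
                      max_generations = cfg$search$max_generations,
                      tol = cfg$search$tol, patience = cfg$search$patience,
                      seed = derive_seed(cfg$seed, 7L),
                      archive_size = cfg$search$archive_size)
  search <- cs_optimize(fitness, dim = length(models), cfg = cs_cfg)
  say("search done: best fitness %.5f at (%s)", search$best_fitness,
      paste(sprintf("%.3f", search$best_weights), collapse = ", "))

  fused_avg <- average_fuse(models)
  fused_opt <- weighted_fuse(models, search$best_weights)

  truth <- eval_manifest$label
  reports <- list(
    model_a = metrics_report(truth, models[[1L]]$probs, scheme, cfg$search$weighting),
    model_b = metrics_report(truth, models[[2L]]$probs, scheme, cfg$search$weighting),
    average_ensemble = metrics_report(truth, fused_avg$probs, scheme, cfg$search$weighting),
    optimized_ensemble = metrics_report(truth, fused_opt$probs, scheme, cfg$search$weighting))

  list(config = cfg, manifest = manifest, test = res$test,
       balanced = balanced, train = split$train,
       validation = split$validation, eval_manifest = eval_manifest,
       models = models, agreement = agreement, search = search,
       fused_average = fused_avg, fused_optimized = fused_opt,
       reports = reports)
}
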