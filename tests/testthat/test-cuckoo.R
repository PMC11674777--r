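# Cuckoo Search: Levy-step construction, population initialization,
# fitness factories, and the optimizer's contract (determinism, elitism,
# bounds, convergence) on analytic and synthetic objectives.

test_that("the Levy scale constant evaluates the closed form", {
  expect_equal(
    (gamma(2.5) * sin(pi * 0.75) / (gamma(1.25) * 1.5 * 2^0.25))^(1 / 1.5),
    cuckoofuse:::levy_sigma(1.5), tolerance = 1e-12)
  expect_equal(cuckoofuse:::levy_sigma(1.5), 0.6966, tolerance = 1e-4)
})

test_that("Levy steps are seed-deterministic and sign-symmetric", {
  s1 <- withr::with_seed(99, levy_step(1.5, 4))
  s2 <- withr::with_seed(99, levy_step(1.5, 4))
  expect_identical(s1, s2)
  expect_error(levy_step(2.5, 2), class = "cf_config_error")

  draws <- withr::with_seed(17, levy_step(1.5, 1e5))
  # sign has mean 0 with SE = 1/sqrt(n)
  expect_lt(abs(mean(sign(draws))), 3 / sqrt(1e5))
})

test_that("nest initialization respects bounds and the seed", {
  cfg <- cs_config(n_nests = 25)
  n1 <- withr::with_seed(5, init_nests(cfg, 2))
  n2 <- withr::with_seed(5, init_nests(cfg, 2))
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(25L, 2L))
  expect_true(all(n1 >= 0 & n1 <= 1))

  narrow <- cs_config(bounds = cbind(c(0.4, 0.4), c(0.6, 0.6)))
  nn <- withr::with_seed(6, init_nests(narrow, 2))
  expect_true(all(nn >= 0.4 & nn <= 0.6))
})

test_that("the accuracy fitness composes fusion, argmax and accuracy", {
  ids <- sprintf("s%d", 1:6)
  truth <- c(1L, 2L, 3L, 4L, 1L, 2L)
  onehot <- function(lab) { m <- matrix(0, length(lab), 4); m[cbind(seq_along(lab), lab)] <- 1; m }
  perfect <- prediction_set("A", ids, onehot(truth), scheme4, truth = truth)
  wrong_lab <- ifelse(truth == 4L, 1L, truth + 1L)
  wrong <- prediction_set("B", ids, onehot(wrong_lab), scheme4, truth = truth)
  fit <- make_accuracy_fitness(list(perfect, wrong))
  expect_equal(fit(c(1, 0)), 1)
  expect_equal(fit(c(0, 1)), 0)
  # hand fusion at equal weights: perfect rows dominate every tie-free row
  fused <- 0.5 * perfect$probs + 0.5 * wrong$probs
  expect_equal(fit(c(0.5, 0.5)), mean(apply(fused, 1, which.max) == truth))

  no_truth <- prediction_set("C", ids, onehot(truth), scheme4)
  expect_error(make_accuracy_fitness(list(no_truth, no_truth)),
               class = "cf_validation_error")
})

test_that("the agreement fitness reproduces Scott's Pi on fused labels and maps undefined to -1", {
  set.seed(43)
  pair <- random_pset_pair(8, scheme4)
  fit <- make_agreement_fitness(pair)
  w <- c(0.6, 0.3)
  fused <- weighted_fuse(pair, w)
  direct <- scotts_pi(pair[[1]]$truth, fused$labels, 4)
  expect_equal(fit(w), if (direct$defined) direct$pi else -1)

  ids <- c("u1", "u2")
  const <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  degen <- prediction_set("D", ids, const, scheme2, truth = c(1L, 1L))
  fit_d <- make_agreement_fitness(list(degen, degen))
  expect_equal(fit_d(c(0.5, 0.5)), -1)
})

test_that("zero generations returns the best of the initial population", {
  fit <- function(w) -sum((w - 0.5)^2)
  cfg <- cs_config(max_generations = 0, seed = 8)
  res <- cs_optimize(fit, 2, cfg)
  nests <- withr::with_seed(8, init_nests(cfg, 2))
  expect_equal(res$best_fitness, max(apply(nests, 1, fit)))
  expect_length(res$history, 1)
})

test_that("the search finds the optimum of a smooth test function", {
  fit <- function(w) -((w[1] - 0.3)^2 + (w[2] - 0.7)^2)
  res <- cs_optimize(fit, 2, cs_config(seed = 1))
  expect_lt(abs(res$best_weights[1] - 0.3), 0.01)
  expect_lt(abs(res$best_weights[2] - 0.7), 0.01)
})

test_that("history is non-decreasing, reruns are identical, and bounds hold", {
  fit <- function(w) sin(7 * w[1]) * cos(3 * w[2]) + w[1]
  for (seed in c(2, 9, 33)) {
    res <- cs_optimize(fit, 2, cs_config(seed = seed, max_generations = 40))
    expect_true(all(diff(res$history) >= 0))
    expect_true(all(res$archive[, 1:2] >= 0 & res$archive[, 1:2] <= 1))
    rerun <- cs_optimize(fit, 2, cs_config(seed = seed, max_generations = 40))
    expect_identical(res[c("best_weights", "best_fitness", "history", "archive")],
                     rerun[c("best_weights", "best_fitness", "history", "archive")])
  }
})

test_that("the archive is sorted, capped and headed by the best solution", {
  fit <- function(w) -sum((w - c(0.2, 0.9))^2)
  res <- cs_optimize(fit, 2, cs_config(seed = 4, archive_size = 5))
  expect_lte(nrow(res$archive), 5)
  expect_true(all(diff(res$archive$fitness) <= 0))
  expect_equal(unname(unlist(res$archive[1, 1:2])), res$best_weights)
  expect_equal(res$archive$fitness[1], res$best_fitness)
})

test_that("non-finite fitness aborts the search naming the weights", {
  fit <- function(w) if (w[1] > 0.5) NaN else w[1]
  expect_error(cs_optimize(fit, 2, cs_config(seed = 12)),
               class = "cf_optimization_error")
})

test_that("search results serialize to JSON with a config echo and history CSV", {
  res <- cs_optimize(function(w) -sum((w - 0.4)^2), 2,
                     cs_config(seed = 3, max_generations = 15))
  path <- withr::local_tempfile(fileext = ".json")
  write_search_result(res, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$best_fitness, res$best_fitness)
  expect_equal(parsed$seed, 3)
  expect_equal(parsed$config$n_nests, 25)
  hist <- read.csv(paste0(path, ".history.csv"))
  expect_equal(hist$best_fitness, res$history)
})

test_that("grid snapping and the weight sweep expose manual-sweep comparisons", {
  expect_equal(snap_to_grid(c(0.512, 0.449)), c(0.5, 0.45))
  set.seed(55)
  pair <- random_pset_pair(30, scheme4)
  fit <- make_accuracy_fitness(pair)
  sweep <- weight_sweep(fit, pitch = 0.25)
  expect_equal(nrow(sweep), 24)  # 5x5 grid minus the all-zero corner
  i <- which(sweep$w1 == 0.5 & sweep$w2 == 0.5)
  expect_equal(sweep$fitness[i], fit(c(0.5, 0.5)))
  # two identical models: fitness constant across the sweep
  twin <- list(pair[[1]],
               prediction_set("twin", pair[[1]]$sample_ids, pair[[1]]$probs,
                              scheme4, truth = pair[[1]]$truth))
  sweep2 <- weight_sweep(make_accuracy_fitness(twin), pitch = 0.25)
  expect_equal(length(unique(sweep2$fitness)), 1)
})
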