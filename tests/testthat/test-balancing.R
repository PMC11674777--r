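# Imbalance protocol: per-class test reservation, resampling to a fixed
# per-class target with replica-id bookkeeping, and stratified splitting.

small_manifest <- function(counts, seed = 1) {
  generate_manifest(counts, scheme4, seed = seed)
}

test_that("reservation draws the ruled counts and fractions per class", {
  man <- small_manifest(c(400, 200, 100, 50))
  rules <- reservation_rules(counts = c(none = 40, very_mild = 40, mild = 40),
                             fractions = c(moderate = 0.2))
  res <- reserve_test_split(man, rules, seed = 2)
  expect_equal(unname(class_counts(res$test)), c(40, 40, 40, 10))
  expect_equal(nrow(res$test) + nrow(res$pool), nrow(man))
  expect_length(intersect(res$test$sample_id, res$pool$sample_id), 0)
  expect_true(all(res$test$split == "test"))
})

test_that("fractional reservations round half-up by default", {
  man <- small_manifest(c(10, 10, 10, 488))
  res <- reserve_test_split(man, reservation_rules(fractions = c(moderate = 0.2)),
                            seed = 3)
  expect_equal(unname(class_counts(res$test)["moderate"]), 98)  # 0.2 * 488 = 97.6
  floor_res <- reserve_test_split(
    man, reservation_rules(fractions = c(moderate = 0.2), rounding = "floor"),
    seed = 3)
  expect_equal(unname(class_counts(floor_res$test)["moderate"]), 97)
})

test_that("empty rules reserve nothing; infeasible rules fail naming the class", {
  man <- small_manifest(c(20, 20, 20, 5))
  res <- reserve_test_split(man, reservation_rules(), seed = 1)
  expect_equal(nrow(res$test), 0)
  expect_equal(sort(res$pool$sample_id), sort(man$sample_id))
  expect_error(reserve_test_split(man, reservation_rules(counts = c(moderate = 10)),
                                  seed = 1),
               "moderate", class = "cf_infeasible_error")
  expect_error(reservation_rules(fractions = c(moderate = 0)),
               class = "cf_config_error")
})

test_that("rebalance hits the target exactly, undersampling without duplicates and oversampling with replica ids", {
  man <- small_manifest(c(10, 2, 5, 5))
  bal <- rebalance(man, target = 5, seed = 7)
  expect_equal(unname(class_counts(bal)), rep(5, 4))
  sc <- attr(bal, "scheme")
  # undersampled class: 5 distinct originals, no replicas
  under <- bal$sample_id[bal$label == 1]
  expect_length(unique(under), 5)
  expect_false(any(grepl("#r", under)))
  # oversampled class: both originals present plus 3 suffixed replicas
  over <- bal$sample_id[bal$label == 2]
  originals <- man$sample_id[man$label == 2]
  expect_true(all(originals %in% over))
  replicas <- grep("#r", over, value = TRUE)
  expect_length(replicas, 3)
  expect_true(all(sub("#r\\d+$", "", replicas) %in% originals))
})

test_that("a pool already at target passes through as a permutation without replicas", {
  man <- small_manifest(c(6, 6, 6, 6))
  bal <- rebalance(man, target = 6, seed = 9)
  expect_setequal(bal$sample_id, man$sample_id)
})

test_that("the rebalanced histogram is constant across seeds", {
  man <- small_manifest(c(30, 3, 12, 7))
  for (seed in 1:5)
    expect_equal(unname(class_counts(rebalance(man, 10, seed = seed))), rep(10, 4))
  empty <- dataset_manifest(c("a", "b"), c(1L, 2L), scheme4)
  expect_error(rebalance(empty, 5, seed = 1), class = "cf_infeasible_error")
})

test_that("stratified splits allocate per class proportionally, disjointly and reproducibly", {
  man <- small_manifest(c(20, 20, 20, 20))
  sp <- stratified_split(man, 60, 20, seed = 5)
  expect_equal(unname(class_counts(sp$train)), rep(15, 4))
  expect_equal(unname(class_counts(sp$validation)), rep(5, 4))
  expect_length(intersect(sp$train$sample_id, sp$validation$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$validation$sample_id), man$sample_id)
  sp2 <- stratified_split(man, 60, 20, seed = 5)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)

  degenerate <- stratified_split(man, 80, 0, seed = 1)
  expect_equal(nrow(degenerate$validation), 0)
  expect_setequal(degenerate$train$sample_id, man$sample_id)
  expect_error(stratified_split(man, 50, 20, seed = 1), class = "cf_validation_error")
})

test_that("unequal classes split exactly under largest-remainder allocation", {
  man <- small_manifest(c(13, 7, 9, 4))
  sp <- stratified_split(man, 25, 8, seed = 11)
  expect_equal(nrow(sp$train), 25)
  expect_equal(nrow(sp$validation), 8)
  expect_equal(class_counts(sp$train) + class_counts(sp$validation),
               class_counts(man))
})

test_that("test manifests never contain replica ids when reservation precedes oversampling", {
  man <- small_manifest(c(50, 8, 30, 12))
  rules <- reservation_rules(counts = c(none = 10, very_mild = 2, mild = 5),
                             fractions = c(moderate = 0.25))
  res <- reserve_test_split(man, rules, seed = 13)
  bal <- rebalance(res$pool, 20, seed = 14)
  expect_false(any(grepl("#r", res$test$sample_id)))
  # replicas exist only in the balanced pool, never leaking into test
  expect_length(intersect(res$test$sample_id, bal$sample_id), 0)
})
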