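# Split schemes, personalization, repeated experiments and the
# training-fraction sweep.

test_that("ratio splits are disjoint, exhaustive and floor-sized", {
  fr <- shared_features("All")
  sp <- shared_split()
  expect_equal(nrow(sp$train), floor(nrow(fr) * 0.8))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(fr))
  key <- function(d) paste(d$participant_id, d$date)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_true(all(sp$train$.partition == "train"))
  expect_true(all(sp$test$.partition == "test"))
  # reproducible under the plan seed
  sp2 <- make_split(fr, split_plan("ratio", 0.8, seed = 1))
  expect_identical(sp$test, sp2$test)
})

test_that("balanced_test holds out exactly n_per_class real rows per class", {
  fr <- shared_features("All")
  sp <- make_split(fr, split_plan("balanced_test", n_per_class = 10,
                                  seed = 2))
  expect_equal(as.integer(table(sp$test$hyper_label)), c(10L, 10L))
  expect_equal(nrow(sp$train), nrow(fr) - 20)
  expect_error(
    make_split(fr, split_plan("balanced_test", n_per_class = 500)),
    "at least 500")
})

test_that("kfold folds partition the data exactly once", {
  fr <- shared_features("All")
  folds <- make_split(fr, split_plan("kfold", n_folds = 10, seed = 3))
  expect_length(folds, 10)
  key <- function(d) paste(d$participant_id, d$date)
  test_keys <- unlist(lapply(folds, function(f) key(f$test)))
  expect_length(test_keys, nrow(fr))
  expect_length(unique(test_keys), nrow(fr))
  sizes <- vapply(folds, function(f) nrow(f$test), 0L)
  expect_lte(diff(range(sizes)), 1)
})

test_that("loso holds out one whole participant per fold", {
  fr <- shared_features("All")
  folds <- make_split(fr, split_plan("loso"))
  expect_length(folds, dplyr::n_distinct(fr$participant_id))
  for (f in folds) {
    expect_length(unique(f$test$participant_id), 1)
    expect_false(unique(f$test$participant_id) %in%
                   f$train$participant_id)
  }
})

test_that("loo yields one fold per row", {
  fr <- shared_features("All")[1:15, ]
  folds <- make_split(fr, split_plan("loo"))
  expect_length(folds, 15)
  expect_true(all(vapply(folds, function(f) nrow(f$test), 0L) == 1))
})

test_that("personalize moves exactly one row of each class into training", {
  fr <- shared_features("All")
  folds <- make_split(fr, split_plan("loso"))
  f <- folds[[1]]
  ps <- personalize(f$train, f$test, seed = 1)
  expect_equal(nrow(ps$train), nrow(f$train) + 2)
  expect_equal(nrow(ps$test), nrow(f$test) - 2)
  moved <- dplyr::anti_join(ps$train, f$train,
                            by = c("participant_id", "date"))
  expect_equal(sort(moved$hyper_label), c(0, 1))
  expect_true(all(moved$.partition == "train"))
  one_class <- f$test[f$test$hyper_label == 0, ]
  expect_error(personalize(f$train, one_class), "each class")
})

test_that("run_experiment is reproducible and averages fold metrics", {
  fr <- shared_features("All")
  cfg <- list(families = "rf")
  r1 <- run_experiment(fr, split_plan("ratio", 0.8), cfg,
                       n_repetitions = 3, seed = 9)
  r2 <- run_experiment(fr, split_plan("ratio", 0.8), cfg,
                       n_repetitions = 3, seed = 9)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3)
  expect_true(all(c("accuracy", "precision", "recall", "f1") %in%
                    names(r1)))
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 1))
  s <- summarise_experiment(r1)
  expect_equal(s$accuracy, mean(r1$accuracy))
})

test_that("regression experiments report NRMSE and tolerance fractions", {
  fr <- shared_features("Sensor+GL")
  r <- run_experiment(fr, split_plan("ratio", 0.8),
                      list(task = "regress_auc",
                           spec = backbone_spec("rf", "regress_auc")),
                      n_repetitions = 2, seed = 4)
  expect_true(all(c("nrmse", "within_5pct", "within_20pct") %in% names(r)))
  expect_true(all(r$nrmse > 0))
  expect_true(all(r$within_5pct <= r$within_20pct))
})

test_that("personalized loso falls back gracefully on one-class folds", {
  fr <- shared_features("All")
  r <- run_experiment(fr, split_plan("loso"),
                      list(families = "rf", personalize = TRUE),
                      n_repetitions = 1, seed = 2)
  expect_equal(nrow(r), 1)
  expect_true(is.finite(r$accuracy))
})

test_that("fraction sweep pairs repetition seeds across fractions", {
  fr <- shared_features("All")
  sw <- fraction_sweep(fr, fractions = c(0.7, 0.9),
                       model_config = list(families = "rf"),
                       n_repetitions = 2, seed = 6)
  expect_equal(sw$train_fraction, c(0.7, 0.9))
  expect_true(all(is.finite(sw$accuracy)))
  # common random numbers: the same repetition permutation is used at each
  # fraction, so the 90% training set contains the whole 70% training set
  plan7 <- split_plan("ratio", 0.7); plan9 <- split_plan("ratio", 0.9)
  plan7$seed <- plan9$seed <- glucolens:::child_seed(6, "rep", 1)
  s7 <- make_split(fr, plan7); s9 <- make_split(fr, plan9)
  key <- function(d) paste(d$participant_id, d$date)
  expect_length(setdiff(key(s7$train), key(s9$train)), 0)
})

test_that("experiment paths never mutate test rows (byte identity)", {
  fr <- shared_features("All")
  sp <- make_split(fr, split_plan("ratio", 0.8, seed = 13))
  before <- serialize(as.data.frame(sp$test), NULL)
  bal <- adasyn_balance(sp$train, seed = 1)
  aug <- gaussian_augment(bal, seed = 1)
  m <- train_ensemble(aug, families = c("rf", "xgb"), seed = 1)
  invisible(predict(m, sp$test, type = "class"))
  expect_identical(serialize(as.data.frame(sp$test), NULL), before)
  # and the partitioned frames never exchange rows
  expect_true(all(bal$.partition == "train"))
  expect_true(all(aug$.partition == "train"))
})
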