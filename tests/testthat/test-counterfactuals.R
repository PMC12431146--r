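# Counterfactual generation contract, quality metrics, and Shapley
# attribution additivity.

test_that("constraint defaults hold the non-actionable features immutable", {
  fx <- cf_fixture()
  expect_setequal(fx$cons$immutable,
                  c("bmi", "day_of_week", "fasting_glucose", "recent_cgm"))
  expect_length(intersect(fx$cons$mutable, fx$cons$immutable), 0)
  expect_setequal(c(fx$cons$mutable, fx$cons$immutable),
                  model_features(fx$split$train))
  expect_error(cf_constraints(fx$split$train, mutable = "bmi"),
               "disjoint")
})

test_that("counterfactuals flip the class within constraints, reproducibly", {
  fx <- cf_fixture()
  q <- fx$split$test[fx$hyper_idx[1], ]
  set <- generate_counterfactuals(fx$model, q, fx$cons, k = 2, seed = 11)
  expect_s3_class(set, "counterfactual_set")
  expect_equal(nrow(set$cfs), 2)
  expect_equal(set$query_class, 1L)
  expect_equal(set$target_class, 0L)
  # every returned row is predicted in the target class
  p <- predict(fx$model, set$cfs, type = "class")
  expect_true(all(p == 0L))
  # immutable features byte-match the query
  for (f in fx$cons$immutable) {
    expect_equal(set$cfs[[f]], rep(q[[f]], 2))
  }
  # perturbed mutable features stay inside the observed training ranges
  # (an unperturbed feature keeps the query's own value, which for a test
  # query may legitimately fall outside the training range)
  for (f in fx$cons$mutable) {
    rg <- fx$cons$ranges[[f]]
    moved <- abs(set$cfs[[f]] - q[[f]]) > 1e-9
    expect_true(all(set$cfs[[f]][moved] >= rg["min"] - 1e-9 &
                      set$cfs[[f]][moved] <= rg["max"] + 1e-9))
  }
  # same seed, same set
  set2 <- generate_counterfactuals(fx$model, q, fx$cons, k = 2, seed = 11)
  expect_equal(set$cfs, set2$cfs)
  expect_equal(set$metrics, set2$metrics)
})

test_that("set metrics match a brute-force recomputation", {
  fx <- cf_fixture()
  q <- fx$split$test[fx$hyper_idx[2], ]
  set <- generate_counterfactuals(fx$model, q, fx$cons, k = 3, seed = 21)
  m <- set$metrics
  feats <- fx$cons$features
  sds <- fx$cons$sds
  n <- nrow(set$cfs)
  # plain-loop recomputation of all four metrics
  d_l1 <- function(a, b) sum(abs(a - b) / sds[feats])
  qv <- as.numeric(q[1, feats])
  prox <- vapply(seq_len(n), function(i)
    d_l1(as.numeric(set$cfs[i, feats]), qv), 0)
  pairs <- utils::combn(n, 2)
  div <- mean(vapply(seq_len(ncol(pairs)), function(c2)
    d_l1(as.numeric(set$cfs[pairs[1, c2], feats]),
         as.numeric(set$cfs[pairs[2, c2], feats])), 0))
  chg <- vapply(seq_len(n), function(i)
    sum(abs(as.numeric(set$cfs[i, feats]) - qv) > 1e-6), 0)
  expect_equal(m$validity, 1)
  expect_equal(m$diversity, div)
  expect_equal(m$normalized_distance, mean(prox))
  expect_equal(m$features_changed, mean(chg))
  expect_equal(m$n_cfs, n)
})

test_that("a single counterfactual has zero diversity by convention", {
  fx <- cf_fixture()
  q <- fx$split$test[fx$hyper_idx[1], ]
  set <- generate_counterfactuals(fx$model, q, fx$cons, k = 1, seed = 5)
  expect_equal(nrow(set$cfs), 1)
  expect_equal(set$metrics$diversity, 0)
})

test_that("an unflippable model yields an honest empty set", {
  fx <- cf_fixture()
  q <- fx$split$test[1, ]
  stubborn <- function(data) rep(0.9, nrow(data))  # always class 1
  set <- generate_counterfactuals(stubborn, q, fx$cons, k = 2, seed = 1,
                                  budget = 500)
  expect_equal(nrow(set$cfs), 0)
  expect_match(set$diagnostic, "no class-flipping")
  expect_true(is.na(set$metrics$validity))
  expect_equal(set$metrics$n_cfs, 0L)
  expect_output(print(set), "note:")
})

test_that("query validation rejects multi-row or incomplete queries", {
  fx <- cf_fixture()
  expect_error(generate_counterfactuals(fx$model, fx$split$test[1:2, ],
                                        fx$cons), "single row")
  q <- fx$split$test[1, ]
  q$bmi <- NA
  expect_error(generate_counterfactuals(fx$model, q, fx$cons), "complete")
})

test_that("tidy() lists changed features; write_explanations emits JSON", {
  fx <- cf_fixture()
  q <- fx$split$test[fx$hyper_idx[1], ]
  set <- generate_counterfactuals(fx$model, q, fx$cons, k = 2, seed = 11)
  td <- tidy(set)
  expect_true(all(td$feature %in% fx$cons$mutable))
  expect_true(all(td$direction %in% c("increase", "decrease")))
  expect_equal(glance(set), set$metrics)
  path <- withr::local_tempfile(fileext = ".json")
  write_explanations(set, path)
  js <- jsonlite::read_json(path)
  expect_named(js, c("query", "query_class", "target_class",
                     "counterfactuals", "changes", "metrics"))
  expect_equal(js$metrics[[1]]$validity, 1)
  expect_length(js$counterfactuals, 2)
})

test_that("permutation Shapley values are exactly additive", {
  fx <- cf_fixture()
  rows <- fx$split$test[1:3, ]
  bg <- fx$split$train[1:25, ]
  sv <- shap_values(fx$model, rows, bg, n_perm = 4, seed = 2)
  expect_equal(dim(sv$values),
               c(3, length(model_features(rows))))
  # sum of attributions telescopes to prediction minus background mean
  expect_equal(rowSums(sv$values), sv$prediction - sv$expected_value,
               tolerance = 1e-10)
  # deterministic under the seed
  sv2 <- shap_values(fx$model, rows, bg, n_perm = 4, seed = 2)
  expect_equal(sv$values, sv2$values)
})

test_that("shap_rank averages trials and ranks descending", {
  fx <- cf_fixture()
  rows <- fx$split$test[1:3, ]
  rk <- shap_rank(fx$model, rows, fx$split$train[1:20, ], n_trials = 2,
                  n_perm = 3, seed = 4)
  expect_setequal(rk$feature, model_features(rows))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$importance) <= 0))
})
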