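# Backbones, metrics, augmentation, balancing and the voting ensemble.

toy_regression <- function(n = 120, seed = 42) {
  withr::with_seed(seed, {
    x1 <- runif(n, 0, 10); x2 <- runif(n, -5, 5)
    tibble::tibble(
      participant_id = "P00", date = as.Date("2024-01-01") + seq_len(n),
      x1 = x1, x2 = x2, iauc = 0, max_bgl = 120 + 3 * x1,
      auc = 300 + 20 * x1 - 10 * x2 + rnorm(n, 0, 2),
      hyper_label = as.integer(x1 + x2 > 6))
  })
}

test_that("backbone_spec validates enumerated variants", {
  expect_error(backbone_spec("rf", n_estimators = 37), "10, 50, 100")
  expect_error(backbone_spec("ridge", alpha = 0.5), "alpha")
  expect_error(backbone_spec("mlp", variant = 14), "variant")
  expect_s3_class(backbone_spec("xgb", "classify_hyper"), "backbone_spec")
})

test_that("model_features excludes identifiers and targets", {
  expect_setequal(model_features(toy_regression()), c("x1", "x2"))
})

test_that("ridge closed form matches the penalized normal equations", {
  d <- toy_regression()
  m <- train_backbone(d, backbone_spec("ridge", "regress_auc", alpha = 1))
  # recompute by hand on the standardized design
  X <- scale(as.matrix(d[c("x1", "x2")]))
  attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  Xc <- cbind(1, X)
  beta <- solve(crossprod(Xc) + diag(c(0, 1, 1)), crossprod(Xc, d$auc))
  expect_equal(m$fit$beta, as.numeric(beta), tolerance = 1e-8)
  expect_equal(predict(m, d), as.numeric(Xc %*% beta), tolerance = 1e-8)
})

test_that("ridge with vanishing penalty approaches ordinary least squares", {
  d <- toy_regression()
  m <- train_backbone(d, backbone_spec("ridge", "regress_auc", alpha = 0.01))
  ols <- lm(auc ~ scale(x1) + scale(x2), data = d)
  expect_equal(unname(m$fit$beta), unname(coef(ols)), tolerance = 1e-3)
})

test_that("rf and xgb regressors learn the toy signal; mlp classifies", {
  d <- toy_regression()
  for (fam in c("rf", "xgb")) {
    m <- train_backbone(d, backbone_spec(fam, "regress_auc"), seed = 1)
    expect_lt(nrmse(d$auc, predict(m, d)), 0.10)
  }
  mc <- train_backbone(d, backbone_spec("mlp", "classify_hyper",
                                        variant = 1), seed = 1)
  acc <- mean(predict(mc, d, type = "class") == d$hyper_label)
  expect_gt(acc, 0.85)
  pr <- predict(mc, d, type = "prob")
  expect_equal(pr$p0 + pr$p1, rep(1, nrow(d)))
})

test_that("training is deterministic under a fixed seed", {
  d <- toy_regression()
  for (fam in c("rf", "xgb", "mlp")) {
    task <- if (fam == "mlp") "classify_hyper" else "regress_auc"
    m1 <- train_backbone(d, backbone_spec(fam, task, variant = 2), seed = 7)
    m2 <- train_backbone(d, backbone_spec(fam, task, variant = 2), seed = 7)
    expect_equal(predict(m1, d), predict(m2, d), tolerance = 1e-12)
  }
})

test_that("constant features are dropped with a warning", {
  d <- toy_regression()
  d$flat <- 5
  expect_warning(m <- train_backbone(d, backbone_spec("ridge", "regress_auc")),
                 "constant feature")
  expect_false("flat" %in% m$features)
  expect_silent(p <- predict(m, d))
})

test_that("class predictions from a regressor are refused", {
  d <- toy_regression()
  m <- train_backbone(d, backbone_spec("ridge", "regress_auc"))
  expect_error(predict(m, d, type = "class"), "classifier")
})

test_that("nrmse and tolerance fractions match hand values", {
  y <- c(100, 200); p <- c(110, 190)
  expect_equal(nrmse(y, p), 10 / 150)
  expect_equal(nrmse(y, p, normalizer = "range"), 10 / 100)
  tf <- tolerance_fractions(y, p)
  # relative errors are 0.10 and 0.05; thresholds are strict (<)
  expect_equal(unname(tf), c(0, 0.5, 1, 1))
  expect_true(all(diff(tf) >= 0))
})

test_that("classification metrics match a hand-worked confusion table", {
  y <- c(1, 1, 1, 0, 0, 0, 0, 0)
  p <- c(1, 1, 0, 0, 0, 0, 1, 1)
  m <- classification_metrics(y, p)
  expect_equal(m$accuracy, 5 / 8)
  prec1 <- 2 / 4; rec1 <- 2 / 3
  prec0 <- 3 / 4; rec0 <- 3 / 5
  expect_equal(m$precision, mean(c(prec0, prec1)))
  expect_equal(m$recall, mean(c(rec0, rec1)))
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(m$f1, mean(c(f1(prec0, rec0), f1(prec1, rec1))))
  # a never-predicted class contributes zero precision, not NaN
  m2 <- classification_metrics(c(0, 1), c(0, 0))
  expect_equal(m2$precision, mean(c(0.5, 0)))
})

test_that("gaussian augmentation appends jittered copies, targets intact", {
  d <- toy_regression(40)
  a <- gaussian_augment(d, sigma = 0.05, multiplier = 2, seed = 9)
  expect_equal(nrow(a), 3 * 40)
  expect_identical(a[1:40, ], d)
  copies <- a[41:80, ]
  expect_equal(copies$auc, d$auc)          # targets copied unchanged
  expect_false(isTRUE(all.equal(copies$x1, d$x1)))
  # jitter scale: sd of the perturbation is near sigma * sd(x1)
  expect_lt(max(abs(copies$x1 - d$x1)), 5 * 0.05 * sd(d$x1))
  # deterministic under the seed
  expect_identical(a, gaussian_augment(d, sigma = 0.05, multiplier = 2,
                                       seed = 9))
})

test_that("adasyn balances classes with synthetic minority segments", {
  d <- toy_regression(100)
  d$hyper_label <- c(rep(1, 20), rep(0, 80))
  a <- adasyn_balance(d, seed = 3)
  tab <- table(a$hyper_label)
  expect_equal(unname(tab["1"]), unname(tab["0"]))
  expect_identical(a[seq_len(nrow(d)), ], d)  # originals untouched, first
  synth <- a[-seq_len(nrow(d)), ]
  expect_true(all(synth$hyper_label == 1))
  # synthetic points lie within the minority bounding box (convex segments)
  minority <- d[d$hyper_label == 1, ]
  for (f in c("x1", "x2")) {
    expect_true(all(synth[[f]] >= min(minority[[f]]) - 1e-9))
    expect_true(all(synth[[f]] <= max(minority[[f]]) + 1e-9))
  }
  # already-balanced data passes through untouched
  expect_identical(adasyn_balance(a, seed = 3), a)
})

test_that("augmentation and balancing refuse test rows", {
  d <- toy_regression(40)
  d$.partition <- c(rep("train", 39), "test")
  expect_error(gaussian_augment(d), "test rows present")
  expect_error(adasyn_balance(d), "test rows present")
})

test_that("soft vote averages member probabilities; ties go positive", {
  d <- toy_regression(80)
  members <- list(
    train_backbone(d, backbone_spec("rf", "classify_hyper"), seed = 1),
    train_backbone(d, backbone_spec("xgb", "classify_hyper"), seed = 2))
  sv <- soft_vote(members, d)
  manual <- (predict(members[[1]], d) + predict(members[[2]], d)) / 2
  expect_equal(sv$p1, manual)
  expect_equal(sv$class, as.integer(manual >= 0.5))
})

test_that("the ensemble trains all members and predicts deterministically", {
  d <- toy_regression(100)
  en <- train_ensemble(d, seed = 5, mlp_variant = 1)
  expect_named(en$members, c("rf", "xgb", "mlp"))
  p1 <- predict(en, d, type = "response")
  en2 <- train_ensemble(d, seed = 5, mlp_variant = 1)
  expect_equal(p1, predict(en2, d, type = "response"), tolerance = 1e-12)
  expect_gt(mean(predict(en, d, type = "class") == d$hyper_label), 0.85)
})

test_that("leaf-limited rf ranks the informative feature first", {
  d <- toy_regression(120)
  d$noise1 <- withr::with_seed(1, runif(120))
  d$noise2 <- withr::with_seed(2, runif(120))
  m <- leaf_limited_rf(d, max_leaf_nodes = 24, task = "regress_auc",
                       seed = 1)
  ranking <- tidy(m)
  expect_equal(ranking$term[1], "x1")
  expect_true(all(c("noise1", "noise2") %in% ranking$term))
})

test_that("mlp layouts enumerate 13 variants", {
  expect_equal(mlp_layout(1), c(20, 10, 5))
  expect_equal(mlp_layout(13), c(160, 80, 40, 40, 40, 40, 20, 10))
  expect_error(mlp_layout(0))
  expect_error(mlp_layout(14))
  layouts <- lapply(1:13, mlp_layout)
  expect_equal(length(unique(lapply(layouts, paste, collapse = "-"))), 13)
})
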