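# Trainable model zoo for AUC / MaxBGL regression and hyperglycemia
# classification, plus evaluation metrics, Gaussian feature augmentation
# and ADASYN class balancing. All stochastic entry points take one explicit
# seed and leave the caller's RNG stream untouched.

#' Backbone specification
#'
#' Families and the enumerated hyperparameter variants: random forest with
#' `n_estimators` in {10, 50, 100}; ridge with penalty `alpha` in
#' {1, 0.1, 0.01}; multilayer perceptron with `variant` in 1..13 (see
#' [mlp_layout()]); gradient boosting (`xgb`) with `nrounds` boosting
#' rounds.
#'
#' @param family `"rf"`, `"ridge"`, `"mlp"` or `"xgb"`.
#' @param task `"regress_auc"`, `"regress_maxbgl"` or `"classify_hyper"`.
#' @param n_estimators Random-forest tree count.
#' @param alpha Ridge penalty weight (per-fit total, intercept unpenalized).
#' @param variant MLP layout index.
#' @param nrounds Boosting rounds for `xgb`.
#' @return A list of class `backbone_spec`.
#' @export
backbone_spec <- function(family = c("rf", "ridge", "mlp", "xgb"),
                          task = c("regress_auc", "regress_maxbgl",
                                   "classify_hyper"),
                          n_estimators = 100, alpha = 1, variant = 13,
                          nrounds = 100) {
  family <- match.arg(family)
  task <- match.arg(task)
  if (family == "rf" && !n_estimators %in% c(10, 50, 100)) {
    abort("rf n_estimators must be one of 10, 50, 100")
  }
  if (family == "ridge" && !alpha %in% c(1, 0.1, 0.01)) {
    abort("ridge alpha must be one of 1, 0.1, 0.01")
  }
  if (family == "mlp") mlp_layout(variant)  # validates
  structure(list(family = family, task = task,
                 n_estimators = as.integer(n_estimators), alpha = alpha,
                 variant = as.integer(variant),
                 nrounds = as.integer(nrounds)),
            class = "backbone_spec")
}

task_target <- function(task) {
  c(regress_auc = "auc", regress_maxbgl = "max_bgl",
    classify_hyper = "hyper_label")[[task]]
}

id_like_cols <- c("participant_id", "date", ".partition",
                  "auc", "iauc", "max_bgl", "hyper_label")

#' Feature columns of a model-ready table
#'
#' Everything that is not an identifier, a partition marker or a target.
#'
#' @param data Feature tibble.
#' @return Character vector of feature column names.
#' @export
model_features <- function(data) {
  setdiff(names(data), id_like_cols)
}

scale_matrix <- function(data, features, center, scale) {
  X <- as.matrix(data[features])
  storage.mode(X) <- "double"
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Train a backbone model
#'
#' Features are standardized with training-only statistics (stored in the
#' model bundle and reapplied at prediction time); constant features are
#' dropped with a warning. Classification targets are the 0/1
#' `hyper_label`.
#'
#' @param data Training tibble of feature rows (see [assemble_features()]).
#' @param spec A [backbone_spec()].
#' @param features Feature columns; defaults to [model_features()].
#' @param seed Integer seed recorded in the bundle.
#' @return A fitted model of class `glucolens_model`.
#' @export
train_backbone <- function(data, spec, features = NULL, seed = 1) {
  if (!inherits(spec, "backbone_spec")) abort("spec must be a backbone_spec")
  features <- features %||% model_features(data)
  target <- task_target(spec$task)
  check_columns(data, c(features, target), "training data")
  if (nrow(data) < 10) abort("need at least 10 training rows")
  classification <- spec$task == "classify_hyper"

  X_raw <- as.matrix(data[features])
  sds <- apply(X_raw, 2, stats::sd)
  dropped <- features[sds == 0 | !is.finite(sds)]
  if (length(dropped) > 0) {
    warn(sprintf("dropping constant feature(s): %s",
                 paste(dropped, collapse = ", ")))
    features <- setdiff(features, dropped)
  }
  center <- colMeans(as.matrix(data[features]))
  scale <- apply(as.matrix(data[features]), 2, stats::sd)
  X <- scale_matrix(data, features, center, scale)
  y <- data[[target]]

  fit <- switch(spec$family,
    rf = with_seed(seed, {
      if (classification) {
        randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = spec$n_estimators)
      } else {
        randomForest::randomForest(X, y, ntree = spec$n_estimators)
      }
    }),
    ridge = ridge_fit(X, y, spec$alpha),
    mlp = mlp_train(X, y, mlp_layout(spec$variant),
                    classification = classification, seed = seed),
    xgb = with_seed(seed, {
      xgboost::xgboost(
        x = X, y = if (classification) factor(y, levels = c(0, 1)) else y,
        nrounds = spec$nrounds, nthreads = 1, max_depth = 4,
        learning_rate = 0.1, seed = seed,
        objective = if (classification) "binary:logistic" else
          "reg:squarederror")
    }))
  structure(list(spec = spec, fit = fit, features = features,
                 dropped = dropped, center = center, scale = scale,
                 classification = classification, seed = seed,
                 n_train = nrow(data)),
            class = "glucolens_model")
}

# closed-form ridge: minimizes ||y - b0 - X b||^2 + alpha ||b||^2
ridge_fit <- function(X, y, alpha) {
  p <- ncol(X)
  Xc <- cbind(1, X)
  pen <- diag(c(0, rep(alpha, p)))
  beta <- solve(crossprod(Xc) + pen, crossprod(Xc, y))
  list(beta = as.numeric(beta), names = c("(Intercept)", colnames(X)))
}

#' Predict from a fitted backbone
#'
#' @param object A `glucolens_model`.
#' @param new_data Tibble containing the model's feature columns.
#' @param type `"response"` (numeric prediction or positive-class
#'   probability), `"prob"` (two-column class-probability tibble) or
#'   `"class"` (0/1 labels; ties go to the positive class).
#' @param ... Unused.
#' @return Numeric vector, or a tibble for `type = "prob"`.
#' @export
predict.glucolens_model <- function(object, new_data,
                                    type = c("response", "prob", "class"),
                                    ...) {
  type <- match.arg(type)
  X <- scale_matrix(new_data, object$features, object$center, object$scale)
  p1 <- switch(object$spec$family,
    rf = {
      if (object$classification) {
        unname(stats::predict(object$fit, X, type = "prob")[, "1"])
      } else unname(stats::predict(object$fit, X))
    },
    ridge = as.numeric(cbind(1, X) %*% object$fit$beta),
    mlp = mlp_predict(object$fit, X),
    xgb = stats::predict(object$fit, X))
  if (!object$classification) {
    if (type != "response") abort("prob/class predictions need a classifier")
    return(p1)
  }
  p1 <- pmin(pmax(p1, 0), 1)
  switch(type,
         response = p1,
         prob = tibble(p0 = 1 - p1, p1 = p1),
         class = as.integer(p1 >= 0.5))
}

#' @export
print.glucolens_model <- function(x, ...) {
  cat(sprintf("<glucolens_model> %s / %s, %d features, n_train = %d\n",
              x$spec$family, x$spec$task, length(x$features), x$n_train))
  invisible(x)
}

#' Normalized root-mean-squared error
#'
#' RMSE divided by the mean of the observed values (an NRMSE of 0.123 reads
#' as predictions within a 12.3% average error margin of the actual
#' values). Range normalization is available behind `normalizer`.
#'
#' @param y_true,y_pred Numeric vectors.
#' @param normalizer `"mean"` (default) or `"range"`.
#' @return NRMSE as a fraction.
#' @export
nrmse <- function(y_true, y_pred, normalizer = c("mean", "range")) {
  normalizer <- match.arg(normalizer)
  rmse <- sqrt(mean((y_true - y_pred)^2))
  rmse / switch(normalizer, mean = mean(y_true),
                range = diff(range(y_true)))
}

#' Fractions of cases within relative error tolerances
#'
#' For each threshold, the fraction of cases with
#' `|y_pred - y_true| / y_true < threshold`.
#'
#' @param y_true,y_pred Numeric vectors.
#' @param thresholds Relative error thresholds as fractions.
#' @return Named numeric vector, nondecreasing in the threshold.
#' @export
tolerance_fractions <- function(y_true, y_pred,
                                thresholds = c(0.05, 0.1, 0.15, 0.2)) {
  rel <- abs(y_pred - y_true) / y_true
  stats::setNames(vapply(thresholds, function(th) mean(rel < th), 0),
                  paste0("within_", thresholds * 100, "pct"))
}

#' Classification metrics (accuracy + macro averages)
#'
#' Macro precision/recall/F1 over the two classes; a class never predicted
#' contributes zero precision, and per-class F1 is zero when both precision
#' and recall are zero.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @return Tibble with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  per_class <- vapply(c(0, 1), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    prec <- if (sum(y_pred == cl) == 0) 0 else tp / sum(y_pred == cl)
    rec <- if (sum(y_true == cl) == 0) 0 else tp / sum(y_true == cl)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }, numeric(3))
  tibble(accuracy = mean(y_true == y_pred),
         precision = mean(per_class[1, ]),
         recall = mean(per_class[2, ]),
         f1 = mean(per_class[3, ]))
}

#' Gaussian feature augmentation of training rows
#'
#' Appends `multiplier * n` jittered copies of the training rows. Noise is
#' drawn per feature as `N(0, (sigma * sd(feature))^2)`, i.e. `sigma` is
#' expressed in standardized units; targets and identifiers are copied
#' unchanged. Refuses to run if any row is marked as a test row.
#'
#' @param data Training feature tibble.
#' @param features Feature columns to jitter; defaults to
#'   [model_features()].
#' @param sigma Noise sd in standardized feature units.
#' @param multiplier How many jittered copies of the data to append.
#' @param seed Integer seed.
#' @return Tibble with original rows first, then the jittered copies.
#' @export
gaussian_augment <- function(data, features = NULL, sigma = 0.05,
                             multiplier = 1, seed = 1) {
  assert_training_only(data, "gaussian_augment")
  features <- features %||% model_features(data)
  if (multiplier < 1) return(data)
  sds <- vapply(data[features], stats::sd, 0)
  copies <- with_seed(seed, {
    purrr::map(seq_len(multiplier), function(m) {
      jit <- data
      for (j in seq_along(features)) {
        jit[[features[j]]] <- jit[[features[j]]] +
          stats::rnorm(nrow(data), 0, sigma * sds[j])
      }
      jit
    })
  })
  dplyr::bind_rows(c(list(data), copies))
}

#' ADASYN class balancing of training rows
#'
#' Adaptive synthetic oversampling of the minority class: each minority row
#' receives synthetic offspring in proportion to the share of
#' majority-class points among its k nearest neighbours (harder
#' neighbourhoods get more), with offspring placed uniformly along segments
#' to randomly chosen minority neighbours in feature space. Test rows are
#' never touched (the function refuses partitioned test rows).
#'
#' @param data Training feature tibble with a 0/1 `label_col`.
#' @param features Feature columns; defaults to [model_features()].
#' @param label_col Name of the 0/1 class column.
#' @param k Neighbourhood size.
#' @param beta Fraction of the class imbalance to synthesize (1 = to
#'   parity).
#' @param seed Integer seed.
#' @return Tibble of original plus synthetic rows, classes near parity.
#' @export
adasyn_balance <- function(data, features = NULL, label_col = "hyper_label",
                           k = 5, beta = 1, seed = 1) {
  assert_training_only(data, "adasyn_balance")
  features <- features %||% model_features(data)
  y <- data[[label_col]]
  counts <- table(factor(y, levels = c(0, 1)))
  if (counts[1] == counts[2]) return(data)
  minority <- as.integer(names(which.min(counts)))
  need <- as.integer(round(beta * abs(diff(as.integer(counts)))))
  min_idx <- which(y == minority)
  if (length(min_idx) < 2 || need == 0) return(data)

  sds <- vapply(data[features], stats::sd, 0)
  sds[sds == 0] <- 1
  Z <- sweep(as.matrix(data[features]), 2, sds, "/")
  D <- as.matrix(stats::dist(Z))
  k_eff <- min(k, nrow(data) - 1)
  r <- vapply(min_idx, function(i) {
    nb <- order(D[i, -i])[seq_len(k_eff)]
    nb_idx <- seq_len(nrow(data))[-i][nb]
    mean(y[nb_idx] != minority)
  }, 0)
  w <- if (sum(r) == 0) rep(1 / length(r), length(r)) else r / sum(r)
  alloc <- floor(need * w)
  rem <- need - sum(alloc)
  if (rem > 0) {
    top <- order(w, decreasing = TRUE)[seq_len(rem)]
    alloc[top] <- alloc[top] + 1L
  }
  synth <- with_seed(seed, {
    purrr::map2_dfr(min_idx, alloc, function(i, g) {
      if (g == 0) return(NULL)
      km <- min(k_eff, length(min_idx) - 1)
      others <- setdiff(min_idx, i)
      nb <- others[order(D[i, others])][seq_len(km)]
      purrr::map_dfr(seq_len(g), function(s) {
        j <- nb[sample.int(length(nb), 1)]
        lam <- stats::runif(1)
        row <- data[i, ]
        for (f in features) {
          row[[f]] <- data[[f]][i] + lam * (data[[f]][j] - data[[f]][i])
        }
        row
      })
    })
  })
  dplyr::bind_rows(data, synth)
}

#' Soft-voting ensemble prediction
#'
#' Unweighted mean of member class-probability vectors; the predicted class
#' is the argmax, with exact ties resolved to the positive class.
#'
#' @param members List of fitted classification `glucolens_model`s.
#' @param new_data Tibble of feature rows.
#' @return Tibble with `p0`, `p1` and `class`.
#' @export
soft_vote <- function(members, new_data) {
  probs <- purrr::map(members, ~ predict(.x, new_data, type = "prob"))
  p1 <- rowMeans(do.call(cbind, purrr::map(probs, "p1")))
  tibble(p0 = 1 - p1, p1 = p1, class = as.integer(p1 >= 0.5))
}

#' Train an RF + XGBoost + MLP soft-voting classifier
#'
#' @param data Training feature tibble with `hyper_label`.
#' @param families Member families (classification backbones).
#' @param features Feature columns; defaults to [model_features()].
#' @param seed Integer seed (member seeds are derived from it).
#' @param mlp_variant MLP layout index for the MLP member.
#' @return A list of class `glucolens_ensemble`.
#' @export
train_ensemble <- function(data, families = c("rf", "xgb", "mlp"),
                           features = NULL, seed = 1, mlp_variant = 13) {
  members <- purrr::map(families, function(fam) {
    train_backbone(data,
                   backbone_spec(fam, "classify_hyper",
                                 variant = mlp_variant),
                   features = features, seed = child_seed(seed, fam))
  })
  structure(list(members = stats::setNames(members, families),
                 features = members[[1]]$features, seed = seed,
                 classification = TRUE),
            class = "glucolens_ensemble")
}

#' @export
predict.glucolens_ensemble <- function(object, new_data,
                                       type = c("response", "prob",
                                                "class"), ...) {
  type <- match.arg(type)
  out <- soft_vote(object$members, new_data)
  switch(type, response = out$p1, prob = out[c("p0", "p1")],
         class = out$class)
}

#' @export
print.glucolens_ensemble <- function(x, ...) {
  cat(sprintf("<glucolens_ensemble> soft vote over: %s\n",
              paste(names(x$members), collapse = " + ")))
  invisible(x)
}

#' Leaf-node-limited random forest
#'
#' A random forest whose trees are capped at `max_leaf_nodes` leaves,
#' usable as a compact feature-selection device: the impurity-gain
#' importances of a capped forest concentrate on the highest-information
#' features.
#'
#' @param data Training feature tibble.
#' @param max_leaf_nodes Leaf cap per tree, one of 24, 48, 96 (or any
#'   positive integer).
#' @param task Regression or classification task.
#' @param features Feature columns; defaults to [model_features()].
#' @param n_estimators Tree count.
#' @param seed Integer seed.
#' @return A `glucolens_model` whose [tidy()] method reports the
#'   impurity-gain feature ranking.
#' @export
leaf_limited_rf <- function(data, max_leaf_nodes = 48,
                            task = "regress_auc", features = NULL,
                            n_estimators = 100, seed = 1) {
  if (max_leaf_nodes < 2) abort("max_leaf_nodes must be >= 2")
  features <- features %||% model_features(data)
  target <- task_target(task)
  classification <- task == "classify_hyper"
  center <- colMeans(as.matrix(data[features]))
  scale <- apply(as.matrix(data[features]), 2, stats::sd)
  keep <- scale > 0 & is.finite(scale)
  features <- features[keep]
  center <- center[keep]; scale <- scale[keep]
  X <- scale_matrix(data, features, center, scale)
  y <- data[[target]]
  fit <- with_seed(seed, {
    if (classification) {
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = n_estimators,
                                 maxnodes = max_leaf_nodes,
                                 importance = TRUE)
    } else {
      randomForest::randomForest(X, y, ntree = n_estimators,
                                 maxnodes = max_leaf_nodes,
                                 importance = TRUE)
    }
  })
  structure(list(spec = structure(list(family = "rf", task = task,
                                       n_estimators = n_estimators,
                                       max_leaf_nodes = max_leaf_nodes),
                                  class = "backbone_spec"),
                 fit = fit, features = features, dropped = character(),
                 center = center, scale = scale,
                 classification = classification, seed = seed,
                 n_train = nrow(data)),
            class = "glucolens_model")
}
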