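# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted backbone
#'
#' Random forests report impurity-based importance, ridge reports
#' coefficients (on standardized features), gradient boosting reports gain,
#' MLPs report layer shapes.
#'
#' @param x A `glucolens_model`.
#' @param ... Unused.
#' @return A tibble; column layout depends on the family.
#' @export
tidy.glucolens_model <- function(x, ...) {
  switch(x$spec$family,
    rf = {
      imp <- randomForest::importance(x$fit)
      gain_col <- ncol(imp)  # IncNodePurity / MeanDecreaseGini is last
      tibble(term = rownames(imp),
             importance = as.numeric(imp[, gain_col])) %>%
        arrange(dplyr::desc(.data$importance))
    },
    ridge = tibble(term = x$fit$names, estimate = x$fit$beta),
    xgb = {
      imp <- xgboost::xgb.importance(model = x$fit)
      tibble(term = imp$Feature, importance = imp$Gain)
    },
    mlp = tibble(
      term = paste0("layer_", seq_along(x$fit$layers)),
      n_in = vapply(x$fit$layers, function(l) nrow(l$W), 0L),
      n_out = vapply(x$fit$layers, function(l) ncol(l$W), 0L)))
}

#' One-row model summary
#'
#' @param x A `glucolens_model`.
#' @param ... Unused.
#' @return Tibble with family, task, sizes and seed.
#' @export
glance.glucolens_model <- function(x, ...) {
  tibble(family = x$spec$family, task = x$spec$task,
         n_features = length(x$features), n_train = x$n_train,
         seed = x$seed)
}

#' @export
tidy.counterfactual_set <- function(x, ...) {
  feats <- x$constraints$features
  if (nrow(x$cfs) == 0) {
    return(tibble(cf = integer(), feature = character(),
                  original = numeric(), counterfactual = numeric(),
                  direction = character()))
  }
  purrr::map_dfr(seq_len(nrow(x$cfs)), function(i) {
    delta <- as.numeric(x$cfs[i, feats]) - as.numeric(x$query[1, feats])
    changed <- which(abs(delta) > 1e-6)
    tibble(cf = i, feature = feats[changed],
           original = as.numeric(x$query[1, feats[changed]]),
           counterfactual = as.numeric(x$cfs[i, feats[changed]]),
           direction = ifelse(delta[changed] > 0, "increase", "decrease"))
  })
}

#' @export
glance.counterfactual_set <- function(x, ...) x$metrics

#' Serialize a counterfactual set to JSON
#'
#' Emits the query, the counterfactual rows, per-feature direction arrows
#' and the set-level metrics.
#'
#' @param set A `counterfactual_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_explanations <- function(set, path) {
  jsonlite::write_json(
    list(query = set$query, query_class = set$query_class,
         target_class = set$target_class, counterfactuals = set$cfs,
         changes = tidy(set), metrics = set$metrics),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
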