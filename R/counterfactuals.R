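# Diverse counterfactual "treatment pathway" generation against the
# hyperglycemia classifier, with the four set-level quality metrics
# (validity, diversity, normalized distance, features changed), plus
# permutation-based Shapley feature attribution.
#
# Distances are L1 in z-scored feature space (per-feature sd taken from the
# training data recorded in the constraints), following the diverse-CF
# method's proximity convention.

# positive-class response for any supported model form
response_of <- function(model, data) {
  if (is.function(model)) return(as.numeric(model(data)))
  stats::predict(model, data, type = "response")
}

#' Counterfactual search constraints
#'
#' Defines which features a counterfactual may move (with ranges clipped to
#' those observed in the training data) and which are immutable. The
#' defaults hold fixed what cannot be retro-acted: BMI, day of week and the
#' two overnight glucose summaries; diet and activity features are mutable.
#'
#' @param data Training feature tibble used for ranges and z-scaling.
#' @param features Feature columns; defaults to [model_features()].
#' @param immutable Features a counterfactual must not change.
#' @param mutable Features allowed to change; defaults to all remaining.
#' @return A list of class `cf_constraints`.
#' @export
cf_constraints <- function(data, features = NULL,
                           immutable = c("bmi", "day_of_week",
                                         "fasting_glucose", "recent_cgm"),
                           mutable = NULL) {
  features <- features %||% model_features(data)
  immutable <- intersect(immutable, features)
  mutable <- mutable %||% setdiff(features, immutable)
  if (length(intersect(mutable, immutable)) > 0) {
    abort("mutable and immutable feature sets must be disjoint")
  }
  ranges <- purrr::map(stats::setNames(mutable, mutable), function(f)
    c(min = min(data[[f]]), max = max(data[[f]])))
  sds <- vapply(data[features], stats::sd, 0)
  sds[sds == 0 | !is.finite(sds)] <- 1
  structure(list(features = features, mutable = mutable,
                 immutable = immutable, ranges = ranges, sds = sds),
            class = "cf_constraints")
}

l1_z <- function(a, b, features, sds) {
  rowSums(abs(sweep(as.matrix(a[features]), 2,
                    as.numeric(b[1, features]))) /
            matrix(sds[features], nrow(a), length(features), byrow = TRUE))
}

#' Generate diverse counterfactuals for one query row
#'
#' Searches over the mutable features with a seeded random-restart scheme:
#' candidate batches perturb 1 to 3 mutable features at a time, with the
#' perturbation radius escalating from local moves toward full observed
#' ranges as the evaluation budget is spent. Candidates that fail to flip
#' the predicted class are discarded; from the valid pool, up to `k`
#' counterfactuals are chosen greedily to maximize
#' `validity margin - lambda_proximity * distance-to-query +
#' lambda_diversity * distance-to-selected`.
#'
#' @param model A classification `glucolens_model`/`glucolens_ensemble`, or
#'   a function mapping a feature tibble to positive-class probabilities.
#' @param query One-row feature tibble.
#' @param constraints A [cf_constraints()].
#' @param k Number of counterfactuals requested.
#' @param seed Integer seed; fixed seeds give identical sets.
#' @param budget Total candidate evaluations allowed.
#' @param lambda_proximity,lambda_diversity Score weights.
#' @return A list of class `counterfactual_set` with `query`, `cfs` (zero
#'   or more rows; never fabricated non-flipping rows), `query_class`,
#'   `target_class`, `constraints` and `metrics` (see
#'   [score_counterfactuals()]). An empty set carries a `diagnostic`
#'   message.
#' @export
generate_counterfactuals <- function(model, query, constraints, k = 2,
                                     seed = 1, budget = 5000,
                                     lambda_proximity = 0.5,
                                     lambda_diversity = 1.0) {
  if (!inherits(constraints, "cf_constraints")) {
    abort("constraints must be built with cf_constraints()")
  }
  if (nrow(query) != 1) abort("query must be a single row")
  feats <- constraints$features
  if (any(is.na(query[feats]))) abort("query row must be complete")
  p_query <- response_of(model, query)
  query_class <- as.integer(p_query >= 0.5)
  target_class <- 1L - query_class

  mut <- constraints$mutable
  batch <- 250L
  n_batches <- max(1L, budget %/% batch)
  pool <- NULL
  with_seed(seed, {
    for (b in seq_len(n_batches)) {
      radius <- min(1, 0.25 + 0.75 * (b - 1) / max(1, n_batches - 1))
      cand <- query[rep(1, batch), ]
      for (i in seq_len(batch)) {
        n_chg <- sample(1:min(3, length(mut)), 1)
        chg <- sample(mut, n_chg)
        for (f in chg) {
          rg <- constraints$ranges[[f]]
          span <- (rg["max"] - rg["min"]) * radius
          val <- if (stats::runif(1) < 0.5) {
            stats::runif(1, max(rg["min"], query[[f]] - span),
                         min(rg["max"], query[[f]] + span))
          } else stats::runif(1, rg["min"], rg["max"])
          cand[i, f] <- val
        }
      }
      p <- response_of(model, cand)
      p_target <- if (target_class == 1L) p else 1 - p
      valid <- cand[p_target >= 0.5, , drop = FALSE]
      if (nrow(valid) > 0) {
        valid$.p_target <- p_target[p_target >= 0.5]
        pool <- dplyr::bind_rows(pool, valid)
      }
      if (!is.null(pool) && nrow(pool) >= 20 * k && b >= 2) break
    }
  })

  if (is.null(pool) || nrow(pool) == 0) {
    set <- structure(list(query = query, cfs = query[0, ],
                          query_class = query_class,
                          target_class = target_class,
                          constraints = constraints,
                          diagnostic = "no class-flipping candidate found within budget",
                          metrics = NULL),
                     class = "counterfactual_set")
    set$metrics <- score_counterfactuals(set)
    return(set)
  }
  pool <- dplyr::distinct(pool, dplyr::across(dplyr::all_of(feats)),
                          .keep_all = TRUE)
  prox <- l1_z(pool, query, feats, constraints$sds)
  base_score <- (pool$.p_target - 0.5) - lambda_proximity * prox
  chosen <- integer(0)
  for (j in seq_len(min(k, nrow(pool)))) {
    score <- base_score
    if (length(chosen) > 0) {
      div_gain <- rowMeans(vapply(chosen, function(ci)
        l1_z(pool, pool[ci, ], feats, constraints$sds),
        numeric(nrow(pool))))
      score <- score + lambda_diversity * div_gain
      score[chosen] <- -Inf
    }
    chosen <- c(chosen, which.max(score))
  }
  cfs <- pool[chosen, , drop = FALSE] %>% select(-".p_target")
  set <- structure(list(query = query, cfs = cfs,
                        query_class = query_class,
                        target_class = target_class,
                        constraints = constraints, diagnostic = NULL,
                        metrics = NULL),
                   class = "counterfactual_set")
  set$metrics <- score_counterfactuals(set)
  set
}

#' Quality metrics of a counterfactual set
#'
#' `validity`: fraction of returned counterfactuals whose predicted class
#' is the target class (1 by construction for nonempty sets, since
#' non-flipping candidates are discarded). `diversity`: mean pairwise L1
#' distance among counterfactuals in z-scored space (0 by convention for a
#' single counterfactual). `normalized_distance`: mean L1 z-distance from
#' the query. `features_changed`: mean count of features differing from
#' the query by more than `tol` in raw units.
#'
#' @param set A `counterfactual_set`.
#' @param tol Raw-unit tolerance for counting a feature as changed.
#' @return Tibble with one row of the four metrics (`NA` for an empty set's
#'   distance metrics).
#' @export
score_counterfactuals <- function(set, tol = 1e-6) {
  feats <- set$constraints$features
  sds <- set$constraints$sds
  n <- nrow(set$cfs)
  if (n == 0) {
    return(tibble(validity = NA_real_, diversity = NA_real_,
                  normalized_distance = NA_real_,
                  features_changed = NA_real_, n_cfs = 0L))
  }
  prox <- l1_z(set$cfs, set$query, feats, sds)
  div <- if (n < 2) 0 else {
    pairs <- utils::combn(n, 2)
    mean(vapply(seq_len(ncol(pairs)), function(c2) {
      l1_z(set$cfs[pairs[1, c2], ], set$cfs[pairs[2, c2], ], feats, sds)
    }, 0))
  }
  changed <- vapply(seq_len(n), function(i)
    sum(abs(as.numeric(set$cfs[i, feats]) -
              as.numeric(set$query[1, feats])) > tol), 0)
  tibble(validity = 1.0, diversity = div,
         normalized_distance = mean(prox),
         features_changed = mean(changed), n_cfs = n)
}

#' @export
print.counterfactual_set <- function(x, ...) {
  cat(sprintf(
    "<counterfactual_set> %d counterfactual(s), class %d -> %d\n",
    nrow(x$cfs), x$query_class, x$target_class))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Permutation Shapley values with a background sample
#'
#' Marginal-contribution attribution along random feature permutations
#' against sampled background rows. Because contributions along each
#' permutation telescope, per-row attributions sum exactly to
#' `prediction - mean(background prediction)`.
#'
#' @param model Model or probability function (see
#'   [generate_counterfactuals()]).
#' @param rows Feature tibble to explain.
#' @param background Background feature tibble (defaults to `rows`).
#' @param features Feature columns; defaults to [model_features()].
#' @param n_perm Permutations per explained row.
#' @param seed Integer seed.
#' @return List with `values` (rows x features matrix), `prediction`,
#'   `expected_value`.
#' @export
shap_values <- function(model, rows, background = rows, features = NULL,
                        n_perm = 10, seed = 1) {
  features <- features %||% model_features(rows)
  d <- length(features)
  n <- nrow(rows)
  nb <- nrow(background)
  plan <- with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      purrr::map(seq_len(n_perm), function(p)
        list(perm = sample(features), b = sample.int(nb, 1)))
    })
  })
  # assemble every intermediate row once, predict in a single batch
  blocks <- vector("list", n * n_perm)
  idx <- 0L
  for (i in seq_len(n)) {
    for (p in seq_len(n_perm)) {
      idx <- idx + 1L
      perm <- plan[[i]][[p]]$perm
      z <- background[rep(plan[[i]][[p]]$b, d + 1), , drop = FALSE]
      for (s in seq_len(d)) {
        got <- perm[seq_len(s)]
        z[s + 1, got] <- rows[i, got]
      }
      blocks[[idx]] <- z
    }
  }
  big <- dplyr::bind_rows(blocks)
  preds <- response_of(model, big)
  values <- matrix(0, n, d, dimnames = list(NULL, features))
  idx <- 0L
  for (i in seq_len(n)) {
    for (p in seq_len(n_perm)) {
      idx <- idx + 1L
      perm <- plan[[i]][[p]]$perm
      off <- (idx - 1L) * (d + 1L)
      seg <- preds[(off + 1L):(off + d + 1L)]
      contrib <- diff(seg)
      values[i, perm] <- values[i, perm] + contrib / n_perm
    }
  }
  ev_rows <- vapply(seq_len(n), function(i)
    mean(vapply(seq_len(n_perm), function(p) {
      off <- ((i - 1L) * n_perm + (p - 1L)) * (d + 1L)
      preds[off + 1L]
    }, 0)), 0)
  list(values = values, prediction = response_of(model, rows),
       expected_value = ev_rows)
}

#' Shapley feature ranking averaged over randomized trials
#'
#' Mean absolute Shapley contribution per feature, averaged over
#' `n_trials` independently seeded runs, ranked descending.
#'
#' @inheritParams shap_values
#' @param n_trials Number of randomized trials to average.
#' @return Tibble `feature`, `importance`, `rank`.
#' @export
shap_rank <- function(model, rows, background = rows, features = NULL,
                      n_trials = 5, n_perm = 10, seed = 1) {
  features <- features %||% model_features(rows)
  per_trial <- purrr::map(seq_len(n_trials), function(tr) {
    sv <- shap_values(model, rows, background, features, n_perm,
                      seed = child_seed(seed, "trial", tr))
    colMeans(abs(sv$values))
  })
  imp <- Reduce(`+`, per_trial) / n_trials
  tibble(feature = features, importance = as.numeric(imp)) %>%
    arrange(dplyr::desc(.data$importance)) %>%
    mutate(rank = dplyr::row_number())
}
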