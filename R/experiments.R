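# Evaluation designs: ratio splits, balanced-test splits, training-fraction
# sweeps, k-fold, leave-one-subject-out and leave-one-out, with optional
# ADASYN balancing, Gaussian augmentation and per-subject personalization.
# Balancing and augmentation always happen after splitting and only ever on
# the training partition; test rows pass through byte-identical.

#' Split plan
#'
#' @param scheme `"ratio"`, `"balanced_test"`, `"kfold"`, `"loso"` or
#'   `"loo"`.
#' @param train_fraction Training fraction for `ratio`
#'   (`floor(n * train_fraction)` training rows).
#' @param n_per_class Held-out real rows per class for `balanced_test`.
#' @param n_folds Folds for `kfold`.
#' @param seed Integer seed.
#' @return A list of class `split_plan`.
#' @export
split_plan <- function(scheme = c("ratio", "balanced_test", "kfold",
                                  "loso", "loo"),
                       train_fraction = 0.8, n_per_class = 10,
                       n_folds = 10, seed = 1) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, train_fraction = train_fraction,
                 n_per_class = as.integer(n_per_class),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "split_plan")
}

mark <- function(data, idx_test) {
  data$.partition <- "train"
  data$.partition[idx_test] <- "test"
  list(train = data[data$.partition == "train", , drop = FALSE],
       test = data[data$.partition == "test", , drop = FALSE])
}

#' Partition feature rows according to a plan
#'
#' `ratio` assigns `floor(n * train_fraction)` rows to training (so 159
#' rows at 80/20 give 127 training and 32 test rows); `balanced_test`
#' removes exactly `n_per_class` real rows per class into the test set;
#' `kfold`, `loso` and `loo` return lists of folds (one test fold per
#' k/participant/row).
#'
#' @param rows Feature tibble (needs `hyper_label` for `balanced_test`,
#'   `participant_id` for `loso`).
#' @param plan A [split_plan()].
#' @return For `ratio`/`balanced_test`: list with `train`, `test` (each
#'   carrying a `.partition` column). For fold schemes: list of such lists.
#' @export
make_split <- function(rows, plan) {
  n <- nrow(rows)
  switch(plan$scheme,
    ratio = {
      n_train <- floor(n * plan$train_fraction)
      idx <- with_seed(plan$seed, sample.int(n))
      mark(rows, idx[(n_train + 1):n])
    },
    balanced_test = {
      y <- rows$hyper_label
      if (min(table(factor(y, levels = c(0, 1)))) < plan$n_per_class) {
        abort(sprintf("each class needs at least %d rows",
                      plan$n_per_class))
      }
      pos <- which(y == 1); neg <- which(y == 0)
      test_idx <- with_seed(plan$seed, c(
        pos[sample.int(length(pos), plan$n_per_class)],
        neg[sample.int(length(neg), plan$n_per_class)]))
      mark(rows, test_idx)
    },
    kfold = {
      fold <- with_seed(plan$seed,
                        sample(rep(seq_len(plan$n_folds), length.out = n)))
      purrr::map(seq_len(plan$n_folds),
                 function(f) mark(rows, which(fold == f)))
    },
    loso = {
      ids <- unique(rows$participant_id)
      purrr::map(ids,
                 function(id) mark(rows, which(rows$participant_id == id)))
    },
    loo = purrr::map(seq_len(n), function(i) mark(rows, i)))
}

#' Personalize a leave-one-subject-out split
#'
#' Moves exactly one positive and one negative row from the test fold into
#' training (a small labeled sample of the held-out subject), keeping the
#' partitions disjoint.
#'
#' @param train,test Feature tibbles from [make_split()].
#' @param seed Integer seed for choosing the moved rows.
#' @return List with updated `train` and `test`.
#' @export
personalize <- function(train, test, seed = 1) {
  pos <- which(test$hyper_label == 1)
  neg <- which(test$hyper_label == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("test fold must contain at least one row of each class")
  }
  # index into the candidate vectors explicitly: sample(x, 1) on a
  # length-one x would draw from 1:x instead
  move <- with_seed(seed, c(pos[sample.int(length(pos), 1)],
                            neg[sample.int(length(neg), 1)]))
  moved <- test[move, , drop = FALSE]
  moved$.partition <- "train"
  list(train = dplyr::bind_rows(train, moved),
       test = test[-move, , drop = FALSE])
}

fit_and_eval <- function(train, test, model_config, seed) {
  features <- model_config$features %||% model_features(train)
  if (isTRUE(model_config$balance)) {
    train <- adasyn_balance(train, features = features,
                            seed = child_seed(seed, "bal"))
  }
  if (isTRUE(model_config$augment)) {
    train <- gaussian_augment(train, features = features,
                              sigma = model_config$sigma %||% 0.05,
                              multiplier = model_config$multiplier %||% 1,
                              seed = child_seed(seed, "aug"))
  }
  task <- model_config$task %||% "classify_hyper"
  if (task == "classify_hyper") {
    fams <- model_config$families %||% c("rf", "xgb", "mlp")
    model <- if (length(fams) > 1) {
      train_ensemble(train, families = fams, features = features,
                     seed = seed,
                     mlp_variant = model_config$mlp_variant %||% 13)
    } else {
      train_backbone(train,
                     backbone_spec(fams, task,
                                   variant = model_config$mlp_variant %||% 13),
                     features = features, seed = seed)
    }
    pred <- stats::predict(model, test, type = "class")
    classification_metrics(test$hyper_label, pred)
  } else {
    spec <- model_config$spec %||% backbone_spec("rf", task)
    model <- train_backbone(train, spec, features = features, seed = seed)
    y <- test[[task_target(task)]]
    pred <- stats::predict(model, test)
    dplyr::bind_cols(tibble(nrmse = nrmse(y, pred)),
                     as_tibble(as.list(tolerance_fractions(y, pred))))
  }
}

#' Run a repeated evaluation experiment
#'
#' Repeats a split / balance / augment / train / evaluate cycle
#' `n_repetitions` times with derived seeds and reports per-repetition
#' metrics plus their means. Balancing and augmentation are applied to the
#' training partition only; for fold schemes metrics are averaged over
#' folds within each repetition. Identical master seeds reproduce the
#' report exactly.
#'
#' @param rows Feature tibble.
#' @param plan A [split_plan()] (its seed is re-derived per repetition).
#' @param model_config List: `task`, `families` (classification),
#'   `spec` (regression), `balance`, `augment`, `personalize`,
#'   `mlp_variant`, `sigma`, `multiplier`, `features`.
#' @param n_repetitions Number of repeated runs.
#' @param seed Master seed.
#' @return Tibble of per-repetition metrics; means are available through
#'   [summarise_experiment()].
#' @export
run_experiment <- function(rows, plan, model_config = list(),
                           n_repetitions = 20, seed = 1) {
  purrr::map_dfr(seq_len(n_repetitions), function(rep_i) {
    rep_seed <- child_seed(seed, "rep", rep_i)
    plan_i <- plan
    plan_i$seed <- rep_seed
    split <- make_split(rows, plan_i)
    folds <- if (!is.null(split$train)) list(split) else split
    fold_metrics <- purrr::imap_dfr(folds, function(fd, fi) {
      train <- fd$train; test <- fd$test
      if (isTRUE(model_config$personalize)) {
        # a held-out subject with only one observed class cannot donate one
        # row per class; such folds are evaluated without personalization
        ps <- tryCatch(personalize(train, test,
                                   seed = child_seed(rep_seed, fi)),
                       error = function(e) NULL)
        if (!is.null(ps)) {
          train <- ps$train; test <- ps$test
        }
      }
      if (nrow(test) == 0) return(NULL)
      fit_and_eval(train, test, model_config,
                   seed = child_seed(rep_seed, "fit", fi))
    })
    fold_metrics %>% summarise(across(dplyr::everything(), mean)) %>%
      mutate(repetition = rep_i, .before = 1)
  })
}

#' Mean metrics of an experiment report
#'
#' @param report Output of [run_experiment()].
#' @return One-row tibble of metric means over repetitions.
#' @export
summarise_experiment <- function(report) {
  report %>% select(-"repetition") %>%
    summarise(across(dplyr::everything(), mean))
}

#' Training-fraction sweep
#'
#' Runs the classification experiment at each training fraction and
#' reports mean metrics per fraction. All fractions share the same
#' repetition seeds (common random numbers): within a repetition every
#' fraction uses the same row permutation, so the training sets are nested
#' and per-fraction means are paired, which sharply reduces the variance of
#' fraction-to-fraction comparisons. The 99% point, whose one-per-class
#' test set makes precision/recall unstable, is reported like the others
#' but should be excluded from monotonicity reasoning.
#'
#' @param rows Feature tibble.
#' @param fractions Training fractions to sweep.
#' @param model_config As in [run_experiment()].
#' @param n_repetitions Repetitions per fraction.
#' @param seed Master seed.
#' @return Tibble with `train_fraction` and mean metrics.
#' @export
fraction_sweep <- function(rows,
                           fractions = c(0.70, 0.75, 0.80, 0.85, 0.90,
                                         0.95),
                           model_config = list(), n_repetitions = 20,
                           seed = 1) {
  purrr::map_dfr(fractions, function(fr) {
    rep <- run_experiment(rows,
                          split_plan("ratio", train_fraction = fr),
                          model_config, n_repetitions, seed = seed)
    summarise_experiment(rep) %>%
      mutate(train_fraction = fr, .before = 1)
  })
}
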