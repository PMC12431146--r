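# Zero-shot language-model prediction interface and the hybrid fusion
# variants. A deterministic mock provider of tunable skill is the provider
# exercised by tests; any object with a `predict_fn(prompt) -> character`
# field can be registered as a provider. Responses are cached per
# (provider, prompt) pair so repeated renderings cost one invocation.

#' Default zero-shot prompt template
#'
#' A task description, a short feature glossary, an `Input:` placeholder
#' (`{input}`) and an instruction to answer with a single number. Only the
#' `Input:` block varies between examples.
#'
#' @return Template string with an `{input}` placeholder.
#' @export
default_prompt_template <- function() {
  paste(
    "You are given one participant-day of lifestyle and glucose data for a",
    "full-time office worker wearing a continuous glucose monitor.",
    "Features: overnight glucose (mg/dL), clock times (fractional hours),",
    "activity durations (seconds), meal nutrition (grams, kcal) and the",
    "meal's glycemic load. Predict the 3-hour postprandial area under the",
    "glucose curve in mg/dL*h after the logged lunch.",
    "Input:",
    "{input}",
    "Respond with a single number and nothing else.",
    sep = "\n")
}

#' Render a feature row into a zero-shot prompt
#'
#' Serializes the feature columns in a fixed order as `name: value` lines
#' and substitutes them into the template's `{input}` placeholder. The same
#' row always renders to the identical prompt.
#'
#' @param row One-row feature tibble (the `"All"` feature set is the
#'   intended input).
#' @param template Prompt template containing `{input}`.
#' @param features Feature columns to serialize; defaults to
#'   [model_features()].
#' @return A list of class `prompt_bundle` with `template_text`,
#'   `rendered_prompt` and `input_block`.
#' @export
render_prompt <- function(row, template = default_prompt_template(),
                          features = NULL) {
  features <- features %||% model_features(row)
  if (nrow(row) != 1) abort("render_prompt takes exactly one row")
  if (!grepl("{input}", template, fixed = TRUE)) {
    abort("template must contain an {input} placeholder")
  }
  vals <- vapply(features, function(f)
    sprintf("%s: %s", f, format(row[[f]], digits = 10, trim = TRUE)), "")
  block <- paste(vals, collapse = "\n")
  structure(list(template_text = template,
                 rendered_prompt = sub("{input}", block, template,
                                       fixed = TRUE),
                 input_block = block),
            class = "prompt_bundle")
}

#' Parse a rendered input block back to feature values
#'
#' Inverse of the serialization used by [render_prompt()]; the mock
#' provider uses this to read features from the prompt text.
#'
#' @param prompt Rendered prompt or input block.
#' @return Named numeric vector of feature values.
#' @export
parse_prompt_input <- function(prompt) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  kv <- regmatches(lines, regexec(
    "^([A-Za-z0-9_]+): (-?[0-9.]+(?:e[+-]?[0-9]+)?)$", lines))
  kv <- kv[lengths(kv) == 3]
  stats::setNames(as.numeric(vapply(kv, `[`, "", 3)),
                  vapply(kv, `[`, "", 2))
}

#' Deterministic mock language-model provider
#'
#' Emulates a zero-shot LLM of tunable skill: it parses the feature values
#' back out of the prompt, forms a linear guess from glycemic load,
#' stepping duration and fasting glucose, and adds noise seeded by the
#' prompt text, so identical prompts always yield identical responses.
#'
#' @param id Provider identifier.
#' @param noise_sd Sd of the prediction noise in mg/dL·h; 0 gives a fully
#'   deterministic skilled provider.
#' @param bias Additive bias in mg/dL·h.
#' @param refuse If `TRUE` the provider declines to answer, exercising the
#'   refusal path.
#' @param seed Base seed mixed with the prompt hash.
#' @return A list of class `llm_provider`.
#' @export
mock_provider <- function(id = "mock", noise_sd = 20, bias = 0,
                          refuse = FALSE, seed = 1) {
  predict_fn <- function(prompt) {
    if (refuse) return("I cannot help with that request.")
    x <- parse_prompt_input(prompt)
    gl <- x[["glycemic_load"]] %||% 25
    stepping <- (x[["stepping_total"]] %||% 1800) / 60
    fasting <- x[["fasting_glucose"]] %||% 95
    guess <- 3 * fasting + 1.85 * (1.6 * gl - 0.25 * stepping) + bias
    eps <- if (noise_sd > 0) {
      with_seed(child_seed(seed, prompt), stats::rnorm(1, 0, noise_sd))
    } else 0
    sprintf("AUC: %.2f", guess + eps)
  }
  structure(list(id = id, predict_fn = predict_fn),
            class = "llm_provider")
}

#' An oracle mock provider returning the true AUC
#'
#' For limit-case testing: responds with the row's true AUC looked up from
#' a reference table keyed by the rendered input block.
#'
#' @param rows Feature tibble with an `auc` column.
#' @param features Feature columns used for rendering.
#' @param id Provider identifier.
#' @return A list of class `llm_provider`.
#' @export
oracle_provider <- function(rows, features = NULL, id = "oracle") {
  features <- features %||% model_features(rows)
  keys <- vapply(seq_len(nrow(rows)), function(i)
    render_prompt(rows[i, ], features = features)$input_block, "")
  lookup <- stats::setNames(rows$auc, keys)
  predict_fn <- function(prompt) {
    x <- parse_prompt_input(prompt)
    block <- paste(vapply(seq_along(x), function(i)
      sprintf("%s: %s", names(x)[i],
              format(x[[i]], digits = 10, trim = TRUE)), ""),
      collapse = "\n")
    val <- unname(lookup[block])
    if (is.na(val)) "unknown example" else sprintf("%.6f", val)
  }
  structure(list(id = id, predict_fn = predict_fn), class = "llm_provider")
}

new_prompt_cache <- function() new.env(parent = emptyenv())

#' Query a provider for one prompt
#'
#' The first numeric token of the response is parsed as the AUC prediction;
#' a response with no finite positive number (a refusal) is marked failed.
#' Up to `retries` re-invocations are attempted. With a cache, identical
#' prompts trigger zero further provider invocations.
#'
#' @param provider An `llm_provider`.
#' @param prompt A `prompt_bundle` or prompt string.
#' @param cache Optional environment from `new_prompt_cache()`.
#' @param retries Re-invocations allowed after an unparseable response.
#' @return A list of class `llm_prediction` with `provider_id`, `auc_pred`
#'   (`NA` on failure), `failed`, `raw_response`, `cache_hit`.
#' @export
predict_with_provider <- function(provider, prompt, cache = NULL,
                                  retries = 2) {
  if (inherits(prompt, "prompt_bundle")) prompt <- prompt$rendered_prompt
  key <- paste0(provider$id, "\r", prompt)
  if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE)) {
    out <- cache[[key]]
    out$cache_hit <- TRUE
    return(out)
  }
  raw <- NULL; val <- NA_real_
  for (attempt in seq_len(retries + 1)) {
    raw <- provider$predict_fn(prompt)
    m <- regmatches(raw, regexpr("-?[0-9]+\\.?[0-9]*(e[+-]?[0-9]+)?", raw))
    if (length(m) == 1) {
      cand <- suppressWarnings(as.numeric(m))
      if (is.finite(cand) && cand > 0) {
        val <- cand
        break
      }
    }
  }
  out <- structure(list(provider_id = provider$id, auc_pred = val,
                        failed = is.na(val), raw_response = raw,
                        cache_hit = FALSE),
                   class = "llm_prediction")
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Zero-shot predictions for a table of feature rows
#'
#' @param rows Feature tibble.
#' @param providers List of `llm_provider`s.
#' @param template Prompt template.
#' @param features Feature columns for rendering.
#' @param cache Optional prompt cache environment.
#' @return Tibble with `.row`, `provider_id`, `auc_pred`, `failed`.
#'   Providers that fail on every row are dropped with a message.
#' @export
llm_predict_rows <- function(rows, providers,
                             template = default_prompt_template(),
                             features = NULL, cache = new_prompt_cache()) {
  features <- features %||% model_features(rows)
  out <- purrr::map_dfr(providers, function(pr) {
    purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      pb <- render_prompt(rows[i, ], template, features)
      pred <- predict_with_provider(pr, pb, cache = cache)
      tibble(.row = i, provider_id = pr$id, auc_pred = pred$auc_pred,
             failed = pred$failed)
    })
  })
  dead <- out %>% group_by(.data$provider_id) %>%
    summarise(all_failed = all(.data$failed)) %>%
    filter(.data$all_failed)
  if (nrow(dead) > 0) {
    inform(sprintf("provider(s) unavailable (all predictions failed): %s",
                   paste(dead$provider_id, collapse = ", ")))
    out <- out %>% filter(!.data$provider_id %in% dead$provider_id)
  }
  out
}

#' Fuse zero-shot predictions into hybrid feature rows
#'
#' `"Hybrid"` appends one `llm_<provider>` column per available provider;
#' `"Hybrid_v2"` appends a single `llm_best` column from the designated
#' best provider; `"Max"` is `Hybrid_v2` followed by Gaussian augmentation
#' of the training partition only (test rows, when marked via
#' `.partition`, are left untouched).
#'
#' @param base_rows Feature tibble (optionally carrying a `.partition`
#'   column with values `"train"`/`"test"`).
#' @param predictions Output of [llm_predict_rows()].
#' @param variant `"Hybrid"`, `"Hybrid_v2"` or `"Max"`.
#' @param best_provider Provider id used by `Hybrid_v2`/`Max`.
#' @param sigma,multiplier,seed Augmentation settings for `"Max"`.
#' @return Augmented feature tibble.
#' @export
build_hybrid_rows <- function(base_rows, predictions,
                              variant = c("Hybrid", "Hybrid_v2", "Max"),
                              best_provider = NULL, sigma = 0.05,
                              multiplier = 1, seed = 1) {
  variant <- match.arg(variant)
  preds <- predictions %>% filter(!.data$failed)
  if (variant == "Hybrid") {
    wide <- preds %>%
      mutate(provider_id = paste0("llm_", .data$provider_id)) %>%
      tidyr::pivot_wider(id_cols = ".row", names_from = "provider_id",
                         values_from = "auc_pred")
    out <- base_rows %>% mutate(.row = dplyr::row_number()) %>%
      inner_join(wide, by = ".row") %>% select(-".row")
    return(out)
  }
  if (is.null(best_provider)) {
    abort("Hybrid_v2/Max require a designated best_provider id")
  }
  best <- preds %>% filter(.data$provider_id == best_provider)
  if (nrow(best) == 0) {
    abort(sprintf("no usable predictions from provider '%s'",
                  best_provider))
  }
  out <- base_rows %>% mutate(.row = dplyr::row_number()) %>%
    inner_join(best %>% select(".row", llm_best = "auc_pred"),
               by = ".row") %>% select(-".row")
  if (variant == "Max") {
    if (".partition" %in% names(out)) {
      train <- out %>% filter(.data$.partition == "train")
      test <- out %>% filter(.data$.partition == "test")
      train <- gaussian_augment(train, sigma = sigma,
                                multiplier = multiplier, seed = seed)
      out <- dplyr::bind_rows(train, test)
    } else {
      out <- gaussian_augment(out, sigma = sigma, multiplier = multiplier,
                              seed = seed)
    }
  }
  out
}
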