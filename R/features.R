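# Feature engineering: glycemic load, activity durations, the self-reported
# activity score, and the five named feature sets.
#
# Feature-set layouts (columns beyond participant_id/date and the targets):
#   common (15): fasting_glucose, recent_cgm, lunch_time, work_from_home,
#     bmi, calories, calories_from_fat, saturated_fat, trans_fat,
#     cholesterol, sodium, total_carbs, sugar, work_start_time, day_of_week
#   sensor (6): sitting_total, standing_total, stepping_total,
#     sitting_at_work, standing_at_work, stepping_at_work  (seconds)
#   self (1):  self_activity_score
#   macro (4): net_carbs, fat, protein, fiber  (consumed grams)
#   gl (1):    glycemic_load
# "Sensor+GL" = common+sensor+gl; "Sensor+Macro" = common+sensor+macro;
# "Self+GL" = common+self+gl; "Self+Macro" = common+self+macro;
# "All" = common+sensor+self+macro+gl.

common_features <- c("fasting_glucose", "recent_cgm", "lunch_time",
                     "work_from_home", "bmi", "calories",
                     "calories_from_fat", "saturated_fat", "trans_fat",
                     "cholesterol", "sodium", "total_carbs", "sugar",
                     "work_start_time", "day_of_week")
sensor_features <- c("sitting_total", "standing_total", "stepping_total",
                     "sitting_at_work", "standing_at_work",
                     "stepping_at_work")
macro_features <- c("net_carbs", "fat", "protein", "fiber")

#' Columns belonging to a named feature set
#'
#' @param feature_set One of `"Sensor+GL"`, `"Sensor+Macro"`, `"Self+GL"`,
#'   `"Self+Macro"`, `"All"`.
#' @return Character vector of feature column names.
#' @export
feature_set_columns <- function(feature_set) {
  sets <- list(
    "Sensor+GL" = c(common_features, sensor_features, "glycemic_load"),
    "Sensor+Macro" = c(common_features, sensor_features, macro_features),
    "Self+GL" = c(common_features, "self_activity_score", "glycemic_load"),
    "Self+Macro" = c(common_features, "self_activity_score", macro_features),
    "All" = c(common_features, sensor_features, "self_activity_score",
              macro_features, "glycemic_load"))
  if (!feature_set %in% names(sets)) {
    abort(sprintf("unknown feature set '%s'; valid sets: %s", feature_set,
                  paste(names(sets), collapse = ", ")))
  }
  sets[[feature_set]]
}

#' Glycemic load of a meal from its macronutrients
#'
#' `GL = 19.27 + 0.39*net_carbs - 0.21*fat - 0.01*protein^2 - 0.01*fiber^2`
#' with the protein and fiber terms squared. Inputs are grams consumed.
#'
#' @param net_carbs,fat,protein,fiber Non-negative grams.
#' @return Glycemic load (unitless); vectorized.
#' @export
glycemic_load <- function(net_carbs, fat, protein, fiber) {
  vals <- cbind(net_carbs, fat, protein, fiber)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("glycemic_load inputs must be finite and >= 0")
  }
  19.27 + 0.39 * net_carbs - 0.21 * fat - 0.01 * protein^2 - 0.01 * fiber^2
}

#' Sitting/standing/stepping durations up to lunch
#'
#' Sums per-class event seconds over two local-clock windows: midnight to
#' lunch (`*_total`) and work start to lunch (`*_at_work`). Events
#' straddling a boundary contribute only their in-window portion. Class
#' mapping: sedentary, seated transport and the lying classes count as
#' sitting; cycling counts as stepping.
#'
#' @param events Single-participant activity tibble
#'   (`start`, `duration`, `activity`).
#' @param date Day of interest.
#' @param lunch_time,work_start Clock times (`hms` or seconds since
#'   midnight).
#' @param class_map Named list mapping the three feature classes to sensor
#'   classes; override to change the aggregation.
#' @return Tibble with the six duration columns, seconds.
#' @export
activpal_durations <- function(events, date, lunch_time, work_start,
                               class_map = list(
                                 sitting = c("sedentary", "seated_transport",
                                             "lying_primary",
                                             "lying_secondary"),
                                 standing = "standing",
                                 stepping = c("stepping", "cycling"))) {
  lunch_h <- frac_hours(hms::as_hms(lunch_time))
  work_h <- frac_hours(hms::as_hms(work_start))
  one <- function(classes, from_h, to_h) {
    window_seconds(events, date, from_h, to_h, classes)
  }
  tibble(
    sitting_total = one(class_map$sitting, 0, lunch_h),
    standing_total = one(class_map$standing, 0, lunch_h),
    stepping_total = one(class_map$stepping, 0, lunch_h),
    sitting_at_work = one(class_map$sitting, work_h, lunch_h),
    standing_at_work = one(class_map$standing, work_h, lunch_h),
    stepping_at_work = one(class_map$stepping, work_h, lunch_h))
}

#' Self-reported activity score from prior same-phase work logs
#'
#' Mean self-reported walking percentage over strictly previous days of the
#' same phase, plus 12 times the mean standing percentage over those days.
#' The current day's own report is never used, so the score carries no
#' same-day leakage.
#'
#' @param work Work-log tibble for one participant.
#' @param current_date The day the score is for.
#' @param phase Phase of `current_date`.
#' @return Score, or `NA` when no prior same-phase day exists.
#' @export
self_activity_score <- function(work, current_date, phase) {
  prior <- work %>%
    filter(.data$phase == !!phase, .data$date < as.Date(current_date))
  if (nrow(prior) == 0) return(NA_real_)
  mean(prior$pct_walking) + 12 * mean(prior$pct_standing)
}

#' Assemble model-ready feature rows for a named feature set
#'
#' Builds one row per logged lunch on a workday: overnight glucose features,
#' meal nutrition (scaled to consumed amounts by the leftover fraction),
#' clock times as fractional hours, day of week as 0 (Mon) - 6 (Sun),
#' sensor durations and/or the self-reported activity score, glycemic load,
#' and the four targets. Rows missing any mandatory feature or target are
#' dropped with an informative count.
#'
#' @param sources List with `cgm`, `activity`, `meals`, `work`, `profiles`
#'   tibbles (a `cohort_bundle` works directly).
#' @param feature_set One of the five named sets; see
#'   [feature_set_columns()].
#' @param horizon_h Postprandial horizon for the targets, hours.
#' @return Tibble with `participant_id`, `date`, the feature columns of the
#'   set, and targets `auc`, `iauc`, `max_bgl`, `hyper_label`.
#' @export
assemble_features <- function(sources, feature_set = "All", horizon_h = 3) {
  cols <- feature_set_columns(feature_set)
  for (nm in c("cgm", "activity", "meals", "work", "profiles")) {
    if (is.null(sources[[nm]])) abort(sprintf("sources$%s is missing", nm))
  }
  targets <- compute_targets(sources$cgm, sources$meals, horizon_h)
  acts <- split(sources$activity, sources$activity$participant_id)
  works <- split(sources$work, sources$work$participant_id)

  rows <- sources$meals %>%
    inner_join(sources$work,
               by = c("participant_id", "date"), suffix = c("", ".work")) %>%
    inner_join(sources$profiles[c("participant_id", "bmi")],
               by = "participant_id") %>%
    inner_join(targets, by = c("participant_id", "date")) %>%
    filter(dow_index(.data$date) < 5)

  built <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    consumed <- r %>%
      mutate(across(dplyr::all_of(meal_nutrients),
                    ~ .x * (1 - .data$leftover_fraction)))
    out <- tibble(
      participant_id = r$participant_id, date = r$date,
      fasting_glucose = r$fasting_glucose, recent_cgm = r$recent_cgm,
      lunch_time = frac_hours(r$meal_time),
      work_from_home = as.numeric(r$work_from_home),
      bmi = r$bmi,
      calories = consumed$calories,
      calories_from_fat = consumed$calories_from_fat,
      saturated_fat = consumed$saturated_fat,
      trans_fat = consumed$trans_fat,
      cholesterol = consumed$cholesterol, sodium = consumed$sodium,
      total_carbs = consumed$total_carbs, sugar = consumed$sugar,
      work_start_time = frac_hours(r$work_start),
      day_of_week = as.numeric(dow_index(r$date)),
      net_carbs = consumed$net_carbs, fat = consumed$fat,
      protein = consumed$protein, fiber = consumed$fiber,
      auc = r$auc, iauc = r$iauc, max_bgl = r$max_bgl,
      hyper_label = r$hyper_label)
    if (any(c(sensor_features) %in% cols)) {
      ev <- acts[[r$participant_id]]
      dur <- activpal_durations(ev, r$date, r$meal_time, r$work_start)
      out <- dplyr::bind_cols(out, dur)
    }
    if ("self_activity_score" %in% cols) {
      out$self_activity_score <- self_activity_score(
        works[[r$participant_id]], r$date, r$phase)
    }
    if ("glycemic_load" %in% cols) {
      out$glycemic_load <- glycemic_load(
        consumed$net_carbs, consumed$fat, consumed$protein, consumed$fiber)
    }
    out
  })
  if (nrow(built) == 0) {
    abort("no participant-day rows could be assembled")
  }
  built <- built[c("participant_id", "date", cols,
                   "auc", "iauc", "max_bgl", "hyper_label")]
  complete <- stats::complete.cases(built[c(cols, "auc", "max_bgl",
                                            "hyper_label")])
  if (any(!complete)) {
    inform(sprintf("assemble_features: dropped %d row(s) with missing %s",
                   sum(!complete), "mandatory features or targets"))
  }
  built[complete, , drop = FALSE]
}
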