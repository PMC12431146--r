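# CGM-derived targets and daily glucose summaries.
#
# All window statistics operate on a single-participant trace tibble with
# `timestamp` and `glucose` columns. Windows are closed on sample
# timestamps; gaps wider than `max_gap_min` inside a postprandial window
# mark that metric missing rather than silently interpolating across them.

trace_day <- function(trace, date) {
  d0 <- as.numeric(at_clock(as.Date(date), hms::hms(0)))
  t <- as.numeric(trace$timestamp)
  trace[t >= d0 & t < d0 + 86400, , drop = FALSE]
}

#' Fasting glucose for a day
#'
#' Minimum CGM reading in the closed 6 AM-10 AM local-clock window.
#'
#' @param trace Single-participant tibble with `timestamp`, `glucose`.
#' @param date The day of interest.
#' @return mg/dL, or `NA` when the window holds no samples.
#' @export
fasting_glucose <- function(trace, date) {
  day <- trace_day(trace, date)
  h <- frac_hours(day$timestamp)
  g <- day$glucose[h >= 6 & h <= 10]
  if (length(g) == 0) NA_real_ else min(g)
}

#' Recent overnight CGM mean
#'
#' Mean CGM reading of the same day from 12 AM (inclusive) to 8 AM
#' (exclusive).
#'
#' @inheritParams fasting_glucose
#' @return mg/dL, or `NA` when the window holds no samples.
#' @export
recent_cgm <- function(trace, date) {
  day <- trace_day(trace, date)
  h <- frac_hours(day$timestamp)
  g <- day$glucose[h >= 0 & h < 8]
  if (length(g) == 0) NA_real_ else mean(g)
}

window_samples <- function(trace, meal_time, horizon_h, max_gap_min) {
  t <- as.numeric(trace$timestamp)
  t0 <- as.numeric(meal_time)
  keep <- t >= t0 - 1e-9 & t <= t0 + horizon_h * 3600 + 1e-9
  w <- trace[keep, , drop = FALSE]
  w <- w[order(w$timestamp), , drop = FALSE]
  if (nrow(w) >= 2 &&
      max(diff(as.numeric(w$timestamp))) > max_gap_min * 60 + 1e-9) {
    return(NULL)  # gap too wide: metric unreliable
  }
  w
}

#' Absolute postprandial area under the glucose curve
#'
#' Trapezoidal integral of glucose versus time over the closed
#' `[meal_time, meal_time + horizon]` window, with time in hours; the value
#' is absolute (not baseline-subtracted). Integration runs between the first
#' and last samples inside the window.
#'
#' @param trace Single-participant tibble with `timestamp`, `glucose`.
#' @param meal_time POSIXct meal time.
#' @param horizon_h Postprandial horizon in hours (default 3).
#' @param max_gap_min Widest tolerated in-window sampling gap, minutes.
#' @return mg/dL·h, or `NA` with fewer than 2 in-window samples or an
#'   over-wide gap.
#' @export
postprandial_auc <- function(trace, meal_time, horizon_h = 3,
                             max_gap_min = 45) {
  w <- window_samples(trace, meal_time, horizon_h, max_gap_min)
  if (is.null(w) || nrow(w) < 2) return(NA_real_)
  th <- as.numeric(w$timestamp) / 3600
  sum(diff(th) * (utils::head(w$glucose, -1) + utils::tail(w$glucose, -1)) / 2)
}

# glucose at meal time by linear interpolation of the bracketing samples
baseline_at <- function(trace, meal_time) {
  t <- as.numeric(trace$timestamp)
  t0 <- as.numeric(meal_time)
  if (all(t < t0) || all(t > t0)) return(NA_real_)
  stats::approx(t, trace$glucose, xout = t0, ties = "ordered")$y
}

#' Incremental postprandial AUC
#'
#' Trapezoidal area of `max(G(t) - G(meal_time), 0)` over the postprandial
#' window; the baseline is the glucose at meal time, linearly interpolated
#' from the bracketing samples. Piecewise-linear segments crossing the
#' baseline are split at the crossing so only the positive part counts.
#'
#' @inheritParams postprandial_auc
#' @return mg/dL·h above baseline, always `>= 0`; `NA` when AUC is missing
#'   or the baseline cannot be interpolated.
#' @export
incremental_auc <- function(trace, meal_time, horizon_h = 3,
                            max_gap_min = 45) {
  w <- window_samples(trace, meal_time, horizon_h, max_gap_min)
  if (is.null(w) || nrow(w) < 2) return(NA_real_)
  b <- baseline_at(trace, meal_time)
  if (is.na(b)) return(NA_real_)
  th <- as.numeric(w$timestamp) / 3600
  y <- w$glucose - b
  total <- 0
  for (i in seq_len(length(th) - 1)) {
    total <- total + positive_trapezoid(th[i], th[i + 1], y[i], y[i + 1])
  }
  total
}

# exact integral of max(linear segment, 0)
positive_trapezoid <- function(x0, x1, y0, y1) {
  if (y0 >= 0 && y1 >= 0) return((x1 - x0) * (y0 + y1) / 2)
  if (y0 <= 0 && y1 <= 0) return(0)
  xc <- x0 + (x1 - x0) * y0 / (y0 - y1)
  if (y0 > 0) (xc - x0) * y0 / 2 else (x1 - xc) * y1 / 2
}

#' Maximum postprandial glucose
#'
#' @inheritParams postprandial_auc
#' @return mg/dL maximum over in-window samples; `NA` when the window is
#'   empty or gapped.
#' @export
max_bgl <- function(trace, meal_time, horizon_h = 3, max_gap_min = 45) {
  w <- window_samples(trace, meal_time, horizon_h, max_gap_min)
  if (is.null(w) || nrow(w) < 1) return(NA_real_)
  max(w$glucose)
}

#' Postprandial hyperglycemia label
#'
#' 1 if the maximum postprandial glucose within the window reaches the
#' 140 mg/dL threshold (inclusive), 0 otherwise.
#'
#' @param max_bgl Maximum postprandial glucose, mg/dL.
#' @param threshold Label threshold, mg/dL.
#' @return Integer 0/1, `NA` when `max_bgl` is missing.
#' @export
hyper_label <- function(max_bgl, threshold = 140) {
  ifelse(is.na(max_bgl), NA_integer_, as.integer(max_bgl >= threshold))
}

#' Per-meal glycemic targets for a cohort
#'
#' Joins each logged lunch to its participant's CGM trace and computes the
#' four outcome variables plus the two overnight glucose features.
#'
#' @param cgm Multi-participant CGM tibble
#'   (`participant_id`, `timestamp`, `glucose`).
#' @param meals Meal tibble (`participant_id`, `date`, `meal_time`, ...).
#' @param horizon_h Postprandial horizon in hours.
#' @param max_gap_min Widest tolerated in-window CGM gap, minutes.
#' @return Tibble with one row per meal: `participant_id`, `date`,
#'   `fasting_glucose`, `recent_cgm`, `auc`, `iauc`, `max_bgl`,
#'   `hyper_label`.
#' @export
compute_targets <- function(cgm, meals, horizon_h = 3, max_gap_min = 45) {
  check_columns(cgm, c("participant_id", "timestamp", "glucose"), "cgm")
  check_columns(meals, c("participant_id", "date", "meal_time"), "meals")
  traces <- split(cgm, cgm$participant_id)
  purrr::pmap_dfr(
    meals[c("participant_id", "date", "meal_time")],
    function(participant_id, date, meal_time) {
      tr <- traces[[participant_id]]
      mt <- at_clock(date, meal_time)
      mb <- if (is.null(tr)) NA_real_ else
        max_bgl(tr, mt, horizon_h, max_gap_min)
      tibble(
        participant_id = participant_id, date = as.Date(date),
        fasting_glucose = if (is.null(tr)) NA_real_ else
          fasting_glucose(tr, date),
        recent_cgm = if (is.null(tr)) NA_real_ else recent_cgm(tr, date),
        auc = if (is.null(tr)) NA_real_ else
          postprandial_auc(tr, mt, horizon_h, max_gap_min),
        iauc = if (is.null(tr)) NA_real_ else
          incremental_auc(tr, mt, horizon_h, max_gap_min),
        max_bgl = mb,
        hyper_label = hyper_label(mb))
    })
}
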