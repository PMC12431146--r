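# Readers and writers for the four raw CSV sources (plus the small
# participants table carrying BMI). Timestamps are ISO-8601, interpreted as
# timezone-naive local clock time. Rows violating invariants are rejected
# with line-numbered diagnostics; structural problems (missing columns,
# overlapping activity events) are hard errors.

meal_nutrients <- c("calories", "calories_from_fat", "saturated_fat",
                    "trans_fat", "cholesterol", "sodium", "total_carbs",
                    "sugar", "net_carbs", "fat", "protein", "fiber")

activity_classes <- c("sedentary", "standing", "stepping", "cycling",
                      "lying_primary", "lying_secondary", "seated_transport")

read_checked <- function(path, required, what) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, required, what)
  df
}

attach_skips <- function(df, bad, what) {
  n_bad <- sum(bad)
  if (n_bad > 0) {
    inform(sprintf("%s: skipped %d invalid row(s) at line(s) %s",
                   what, n_bad,
                   paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  }
  out <- df[!bad, , drop = FALSE]
  attr(out, "n_skipped") <- n_bad
  out
}

#' Read a CGM trace file
#'
#' Expects columns `participant_id`, `timestamp` (ISO-8601 local clock) and
#' `glucose` (mg/dL). Readings outside the plausible 20-500 mg/dL range are
#' skipped with a line-numbered message; duplicate (participant, timestamp)
#' rows keep the first occurrence. The returned tibble is sorted by
#' participant and time.
#'
#' @param path CSV file path.
#' @return Tibble `participant_id`, `timestamp`, `glucose`, with an
#'   `n_skipped` attribute counting rejected rows.
#' @export
read_cgm <- function(path) {
  df <- read_checked(path, c("participant_id", "timestamp", "glucose"),
                     "cgm file")
  df$timestamp <- parse_naive_time(df$timestamp)
  bad <- is.na(df$timestamp) | !is.finite(df$glucose) |
    df$glucose < 20 | df$glucose > 500
  df <- attach_skips(df, bad, "read_cgm")
  n_skipped <- attr(df, "n_skipped")
  out <- df %>%
    distinct(.data$participant_id, .data$timestamp, .keep_all = TRUE) %>%
    arrange(.data$participant_id, .data$timestamp)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read an activity event log
#'
#' Expects columns `participant_id`, `start`, `duration` (seconds) and
#' `activity` (one of the seven thigh-sensor classes). Overlapping events
#' within a participant are a validation error naming the offending lines.
#'
#' @param path CSV file path.
#' @return Tibble of events sorted by participant and start time.
#' @export
read_activity <- function(path) {
  df <- read_checked(path, c("participant_id", "start", "duration",
                             "activity"), "activity file")
  df$start <- parse_naive_time(df$start)
  bad <- is.na(df$start) | !is.finite(df$duration) | df$duration <= 0 |
    !(df$activity %in% activity_classes)
  df <- attach_skips(df, bad, "read_activity")
  n_skipped <- attr(df, "n_skipped")
  df <- df %>% mutate(.line = dplyr::row_number() + 1L) %>%
    arrange(.data$participant_id, .data$start)
  ends <- as.numeric(df$start) + df$duration
  same <- df$participant_id == dplyr::lag(df$participant_id)
  # sub-millisecond slack absorbs truncation in fractional-second text
  overlap <- which(!is.na(same) & same &
                     as.numeric(df$start) < dplyr::lag(ends) - 1e-3)
  if (length(overlap) > 0) {
    i <- overlap[1]
    abort(sprintf(
      "overlapping activity events for %s at lines %d and %d",
      df$participant_id[i], df$.line[i - 1], df$.line[i]))
  }
  out <- df %>% select(-".line")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a food log
#'
#' Expects `participant_id`, `date`, `meal_time` (HH:MM[:SS]) plus the
#' nutrition-facts columns and `leftover_fraction`. Rows with negative
#' nutrients, `net_carbs > total_carbs`, or leftover fractions outside
#' `[0, 1]` are skipped. Nutrient amounts are as listed; consumed amounts
#' are listed times `(1 - leftover_fraction)`.
#'
#' @param path CSV file path.
#' @return Tibble of meal records.
#' @export
read_meals <- function(path) {
  df <- read_checked(path, c("participant_id", "date", "meal_time",
                             meal_nutrients, "leftover_fraction"),
                     "food log")
  df$date <- as.Date(df$date)
  df$meal_time <- hms::as_hms(df$meal_time)
  nut <- as.matrix(df[meal_nutrients])
  bad <- is.na(df$date) | is.na(df$meal_time) |
    rowSums(!is.finite(nut) | nut < 0) > 0 |
    df$net_carbs > df$total_carbs + 1e-9 |
    df$leftover_fraction < 0 | df$leftover_fraction > 1
  attach_skips(df, bad, "read_meals")
}

#' Read a work log
#'
#' Expects `participant_id`, `date`, `work_start`, `work_end` (HH:MM[:SS]),
#' `work_from_home` (0/1), the three self-reported percentages and `phase`.
#' Rows whose percentages sum above 100 or whose start is not before the end
#' are skipped.
#'
#' @param path CSV file path.
#' @return Tibble of work records.
#' @export
read_work <- function(path) {
  df <- read_checked(path, c("participant_id", "date", "work_start",
                             "work_end", "work_from_home", "pct_sitting",
                             "pct_standing", "pct_walking", "phase"),
                     "work log")
  df$date <- as.Date(df$date)
  df$work_start <- hms::as_hms(df$work_start)
  df$work_end <- hms::as_hms(df$work_end)
  pct <- df$pct_sitting + df$pct_standing + df$pct_walking
  bad <- is.na(df$date) | is.na(df$work_start) | is.na(df$work_end) |
    df$work_start >= df$work_end | !is.finite(pct) | pct > 100 + 1e-6 |
    df$pct_sitting < 0 | df$pct_standing < 0 | df$pct_walking < 0 |
    !(df$work_from_home %in% c(0, 1))
  attach_skips(df, bad, "read_work")
}

#' Read the participants table (enrollment BMI)
#' @param path CSV with `participant_id`, `bmi`.
#' @return Tibble of participant profiles.
#' @export
read_profiles <- function(path) {
  df <- read_checked(path, c("participant_id", "bmi"), "participants file")
  attach_skips(df, !is.finite(df$bmi) | df$bmi <= 0, "read_profiles")
}

parse_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(format(x, "%Y-%m-%d %H:%M:%OS6"), tz = gl_tz,
                      format = "%Y-%m-%d %H:%M:%OS"))
  }
  x <- gsub("T", " ", as.character(x))
  as.POSIXct(x, tz = gl_tz,
             tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
}

# %OS6 keeps sub-second event boundaries so contiguous tilings survive a
# disk round-trip without spurious overlaps
fmt_naive_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS6")

#' Writers for the raw CSV dialects
#'
#' Inverse of the corresponding readers; `read_*(write_*(x))` is
#' field-equivalent to `x`.
#'
#' @param x Tibble in the reader's layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @name log_writers
NULL

#' @rdname log_writers
#' @export
write_cgm <- function(x, path) {
  x$timestamp <- fmt_naive_time(x$timestamp)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname log_writers
#' @export
write_activity <- function(x, path) {
  x$start <- fmt_naive_time(x$start)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname log_writers
#' @export
write_meals <- function(x, path) {
  x$meal_time <- format(hms::as_hms(x$meal_time))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname log_writers
#' @export
write_work <- function(x, path) {
  x$work_start <- format(hms::as_hms(x$work_start))
  x$work_end <- format(hms::as_hms(x$work_end))
  readr::write_csv(x, path)
  invisible(path)
}

#' Read all sources from a directory
#'
#' Convenience wrapper expecting the five standard file names under `dir`:
#' `cgm.csv`, `activpal_events.csv`, `food_log.csv`, `work_log.csv`,
#' `participants.csv`.
#'
#' @param dir Directory holding the raw CSVs.
#' @return List with `cgm`, `activity`, `meals`, `work`, `profiles`.
#' @export
read_cohort_dir <- function(dir) {
  list(cgm = read_cgm(file.path(dir, "cgm.csv")),
       activity = read_activity(file.path(dir, "activpal_events.csv")),
       meals = read_meals(file.path(dir, "food_log.csv")),
       work = read_work(file.path(dir, "work_log.csv")),
       profiles = read_profiles(file.path(dir, "participants.csv")))
}
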