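#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Clock/time helpers -----------------------------------------------------
# All timestamps are timezone-naive local clock time, represented as POSIXct
# in UTC so arithmetic never crosses DST.

#' @keywords internal
gl_tz <- "UTC"

# fractional hours since midnight for POSIXct or hms
frac_hours <- function(x) {
  if (inherits(x, "POSIXct")) {
    lt <- as.POSIXlt(x, tz = gl_tz)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else if (inherits(x, "hms") || inherits(x, "difftime")) {
    as.numeric(x, units = "secs") / 3600
  } else {
    as.numeric(x)
  }
}

# combine a Date and an hms clock time into naive POSIXct
at_clock <- function(date, clock) {
  as.POSIXct(as.numeric(as.POSIXct(date, tz = gl_tz)) +
               as.numeric(clock, units = "secs"),
             origin = "1970-01-01", tz = gl_tz)
}

# day-of-week as integer 0 (Monday) .. 6 (Sunday)
dow_index <- function(date) {
  (as.integer(format(as.Date(date), "%u")) - 1L)
}

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a reproducible child seed, kept within 32-bit integer range
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  codes <- utf8ToInt(key)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# assert a data frame has the given columns
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# guard: error if any row of a partitioned table is a test row
assert_training_only <- function(data, what) {
  if (".partition" %in% names(data) && any(data$.partition == "test")) {
    abort(sprintf("%s must only be applied to training rows; test rows present",
                  what))
  }
  invisible(data)
}
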