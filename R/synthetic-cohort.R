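# Synthetic multimodal cohort with known ground-truth effect structure.
#
# Emulates a worksite sedentary-behavior trial: full-time workers wear a
# 15-min CGM and a thigh-worn activity sensor, receive a standardized
# delivered lunch on workdays, and log meals and work timing across three
# phases (Baseline, then Stand and Move interventions in randomized order).
# Meal excursion amplitude rises with glycemic load and pre-lunch sitting
# and falls with pre-lunch stepping, so downstream models have a learnable,
# recoverable signal.

#' Ground-truth effect parameters for the synthetic cohort
#'
#' The generating model for the postprandial excursion amplitude is
#' `A = gl_effect * GL - stepping_effect * stepping_min + sitting_effect * sitting_h`,
#' clipped at zero. These parameters are retained alongside generated data so
#' parameter-recovery tests can confirm the embedded signal.
#'
#' @param gl_effect mg/dL of peak rise per glycemic-load unit.
#' @param stepping_effect mg/dL of peak reduction per minute of pre-lunch stepping.
#' @param sitting_effect mg/dL of peak rise per hour of at-work pre-lunch sitting.
#' @param baseline_glucose_mean,baseline_glucose_sd Between-participant
#'   fasting baseline distribution, mg/dL.
#' @param noise_sd Per-sample CGM measurement noise, mg/dL.
#' @return A list of class `ground_truth_params`.
#' @export
ground_truth_params <- function(gl_effect = 1.6,
                                stepping_effect = 0.25,
                                sitting_effect = 4,
                                baseline_glucose_mean = 95,
                                baseline_glucose_sd = 8,
                                noise_sd = 4) {
  vals <- c(gl_effect = gl_effect, stepping_effect = stepping_effect,
            sitting_effect = sitting_effect,
            baseline_glucose_mean = baseline_glucose_mean,
            baseline_glucose_sd = baseline_glucose_sd, noise_sd = noise_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all ground-truth parameter magnitudes must be finite and >= 0")
  }
  structure(as.list(vals), class = "ground_truth_params")
}

#' Cohort generation configuration
#'
#' @param n_participants Number of participants (>= 1).
#' @param n_phases Number of study phases; 3 gives Baseline/Stand/Move.
#' @param workdays_per_phase Workdays (Mon-Fri) per phase.
#' @param cgm_interval CGM cadence in minutes; must divide 60.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param effect_params A [ground_truth_params()] list.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 10,
                          n_phases = 3,
                          workdays_per_phase = 5,
                          cgm_interval = 15,
                          seed = 1,
                          effect_params = ground_truth_params()) {
  if (n_participants < 1 || workdays_per_phase < 1 || n_phases < 1) {
    abort("n_participants, n_phases and workdays_per_phase must be positive")
  }
  if (cgm_interval <= 0 || 60 %% cgm_interval != 0) {
    abort("cgm_interval must be a positive divisor of 60 minutes")
  }
  if (!inherits(effect_params, "ground_truth_params")) {
    abort("effect_params must be built with ground_truth_params()")
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_phases = as.integer(n_phases),
                 workdays_per_phase = as.integer(workdays_per_phase),
                 cgm_interval = as.integer(cgm_interval),
                 seed = as.integer(seed),
                 effect_params = effect_params),
            class = "cohort_config")
}

#' Unimodal postprandial response kernel
#'
#' Gamma-shaped kernel `r(u) = u * exp(1 - u)` for `u >= 0`, zero otherwise:
#' rises from `r(0) = 0` to a peak of exactly 1 at `u = 1`, then decays.
#' With the default time constant of 45 min the excursion peaks 45 min after
#' the meal and has largely decayed within 3 h.
#'
#' @param u Time since the meal divided by the kernel time constant.
#' @return Kernel values in `[0, 1]`.
#' @export
glucose_response_kernel <- function(u) {
  ifelse(u > 0, u * exp(1 - u), 0)
}

#' Meal excursion amplitude under the generating model
#'
#' @param gl Glycemic load of the meal (unitless).
#' @param stepping_min Minutes of stepping from midnight until the meal.
#' @param sitting_h Hours of at-work sitting until the meal.
#' @param params A [ground_truth_params()] list.
#' @return Peak excursion amplitude in mg/dL, clipped at >= 0.
#' @export
meal_amplitude <- function(gl, stepping_min, sitting_h, params) {
  pmax(0, params$gl_effect * gl -
         params$stepping_effect * stepping_min +
         params$sitting_effect * sitting_h)
}

#' Simulate one participant-day CGM trace
#'
#' Glucose is baseline plus a sum of meal responses plus Gaussian noise:
#' `G(t) = baseline + sum_m A_m * r((t - t_m) / tau) + eps`, floored at a
#' physiologic 40 mg/dL. Meal amplitudes follow [meal_amplitude()].
#'
#' @param date A `Date`; the trace covers `00:00` to `23:45` local clock.
#' @param meals Tibble with columns `time_h` (fractional hours), `gl`,
#'   `stepping_min`, `sitting_h`. Use zeros for unlogged background meals
#'   whose activity context should not matter.
#' @param baseline Fasting baseline glucose, mg/dL.
#' @param params A [ground_truth_params()] list.
#' @param interval_min CGM cadence in minutes.
#' @param tau_min Kernel time constant, minutes.
#' @param seed Optional integer seed for the noise draw.
#' @return Tibble with `timestamp` and `glucose` columns.
#' @export
simulate_cgm_day <- function(date, meals, baseline,
                             params = ground_truth_params(),
                             interval_min = 15, tau_min = 45, seed = NULL) {
  date <- as.Date(date)
  grid_h <- seq(0, 24 - interval_min / 60, by = interval_min / 60)
  g <- rep(baseline, length(grid_h))
  if (nrow(meals) > 0) {
    amp <- meal_amplitude(meals$gl, meals$stepping_min, meals$sitting_h, params)
    for (i in seq_len(nrow(meals))) {
      u <- (grid_h - meals$time_h[i]) * 60 / tau_min
      g <- g + amp[i] * glucose_response_kernel(u)
    }
  }
  if (params$noise_sd > 0) {
    eps <- if (is.null(seed)) stats::rnorm(length(g), 0, params$noise_sd) else
      with_seed(seed, stats::rnorm(length(g), 0, params$noise_sd))
    g <- g + eps
  }
  tibble(timestamp = at_clock(date, hms::hms(hours = grid_h)),
         glucose = pmax(40, g))
}

# activity-class composition by day period and phase
period_mix <- function(period, phase) {
  switch(period,
    morning = c(sedentary = 0.45, standing = 0.30, stepping = 0.25),
    work = switch(phase,
      Stand = c(sedentary = 0.60, standing = 0.30, stepping = 0.10),
      Move  = c(sedentary = 0.60, standing = 0.20, stepping = 0.20),
      c(sedentary = 0.70, standing = 0.20, stepping = 0.10)),
    leisure = c(sedentary = 0.55, standing = 0.20, stepping = 0.20,
                cycling = 0.05),
    evening = c(sedentary = 0.60, standing = 0.20, stepping = 0.15,
                cycling = 0.05))
}

# tile [start_h, end_h) with non-overlapping bouts drawn from a class mix
tile_period <- function(date, start_h, end_h, mix) {
  out <- list()
  t <- start_h * 3600
  end_s <- end_h * 3600
  k <- 0L
  while (t < end_s - 1e-9) {
    cls <- sample(names(mix), 1, prob = mix)
    dur <- max(60, stats::rgamma(1, shape = 2, scale = 600))
    dur <- min(dur, end_s - t)
    k <- k + 1L
    out[[k]] <- list(start_s = t, duration = dur, activity = cls)
    t <- t + dur
  }
  if (k == 0L) {
    return(tibble(start = at_clock(date, hms::hms(0))[0],
                  duration = numeric(), activity = character()))
  }
  df <- dplyr::bind_rows(out)
  df$start <- at_clock(date, hms::hms(seconds = df$start_s))
  df[c("start", "duration", "activity")]
}

# one full day of activity events, tiling midnight to midnight
simulate_day_events <- function(date, phase, is_workday,
                                work_start_h = NA, work_end_h = NA,
                                wfh = 0L) {
  wake_h <- stats::rnorm(1, 6.4, 0.25)
  bed_h <- stats::rnorm(1, 22.5, 0.3)
  segs <- list(tibble(start = at_clock(date, hms::hms(hours = 0)),
                      duration = wake_h * 3600, activity = "lying_primary"))
  if (is_workday) {
    commute <- if (wfh == 0L) stats::runif(1, 15, 30) / 60 else 0
    segs <- c(segs,
      list(tile_period(date, wake_h, work_start_h - commute,
                       period_mix("morning", phase))))
    if (commute > 0) {
      segs <- c(segs, list(tibble(
        start = at_clock(date, hms::hms(hours = work_start_h - commute)),
        duration = commute * 3600, activity = "seated_transport")))
    }
    segs <- c(segs,
      list(tile_period(date, work_start_h, work_end_h,
                       period_mix("work", phase)),
           tile_period(date, work_end_h, bed_h,
                       period_mix("evening", phase))))
  } else {
    segs <- c(segs,
      list(tile_period(date, wake_h, bed_h, period_mix("leisure", phase))))
  }
  segs <- c(segs, list(tibble(
    start = at_clock(date, hms::hms(hours = bed_h)),
    duration = (24 - bed_h) * 3600, activity = "lying_secondary")))
  dplyr::bind_rows(segs)
}

# one delivered-lunch nutrition draw; listed (pre-leftover) amounts
draw_meal <- function() {
  total_carbs <- min(120, max(15, stats::rnorm(1, 62, 15)))
  fiber <- min(15, max(0.5, stats::rnorm(1, 6, 2.5)))
  fat <- min(60, max(5, stats::rnorm(1, 25, 8)))
  protein <- min(70, max(8, stats::rnorm(1, 30, 10)))
  leftover <- if (stats::runif(1) < 0.7) 0 else stats::runif(1, 0.05, 0.35)
  tibble(
    calories = 4 * (total_carbs + protein) + 9 * fat +
      abs(stats::rnorm(1, 0, 20)),
    calories_from_fat = 9 * fat,
    saturated_fat = 0.3 * fat * stats::runif(1, 0.7, 1.3),
    trans_fat = abs(stats::rnorm(1, 0, 0.3)),
    cholesterol = max(0, stats::rnorm(1, 60, 25)),
    sodium = max(100, stats::rnorm(1, 900, 250)),
    total_carbs = total_carbs,
    sugar = total_carbs * stats::runif(1, 0.15, 0.45),
    net_carbs = total_carbs - fiber,
    fat = fat, protein = protein, fiber = fiber,
    leftover_fraction = leftover)
}

# per-class seconds inside a clock window, clipping straddling events
window_seconds <- function(events, date, from_h, to_h, classes) {
  w0 <- as.numeric(at_clock(date, hms::hms(hours = from_h)))
  w1 <- as.numeric(at_clock(date, hms::hms(hours = to_h)))
  s <- as.numeric(events$start)
  e <- s + events$duration
  ov <- pmax(0, pmin(e, w1) - pmax(s, w0))
  sum(ov[events$activity %in% classes])
}

#' Generate a complete synthetic multimodal cohort
#'
#' Produces CGM traces, activity event logs, food logs, work logs and
#' participant profiles for `n_participants` over `n_phases` phases of
#' `workdays_per_phase` workdays each (weekends are generated in the CGM and
#' activity streams but carry no meal or work rows). Phase order is Baseline
#' first, then the Stand and Move interventions in per-participant random
#' order. Exactly one lunch meal is logged per workday; self-reported work
#' percentages are the true sensor-derived percentages plus truncated
#' Gaussian reporting error (sd 5 points).
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_bundle` with tibbles `cgm`, `activity`,
#'   `meals`, `work`, `profiles`, plus `params` and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("config must be built with cohort_config()")
  }
  params <- config$effect_params
  with_seed(config$seed, {
    phase_names <- c("Baseline", "Stand", "Move")[seq_len(config$n_phases)]
    start_monday <- as.Date("2024-01-01")  # a Monday
    n_weeks <- ceiling(config$workdays_per_phase / 5) * config$n_phases
    all_days <- seq(start_monday, by = 1, length.out = n_weeks * 7 + 7)

    cgm_l <- list(); act_l <- list(); meal_l <- list(); work_l <- list()
    profiles <- vector("list", config$n_participants)

    for (p in seq_len(config$n_participants)) {
      pid <- sprintf("P%02d", p)
      prof <- list(
        participant_id = pid,
        bmi = stats::rnorm(1, 32.8, 4.5),
        habitual_lunch = 12.5 + stats::rnorm(1, 0, 0.3),
        habitual_work_start = 8.5 + stats::rnorm(1, 0, 0.4),
        wfh_probability = stats::rbeta(1, 2, 5),
        baseline = stats::rnorm(1, params$baseline_glucose_mean,
                                params$baseline_glucose_sd))
      profiles[[p]] <- tibble(participant_id = pid, bmi = prof$bmi,
                              habitual_lunch_time = prof$habitual_lunch,
                              habitual_work_start = prof$habitual_work_start,
                              wfh_probability = prof$wfh_probability)
      order_rest <- if (config$n_phases >= 3) sample(c("Stand", "Move")) else
        phase_names[-1]
      phases_p <- c("Baseline", order_rest)[seq_len(config$n_phases)]

      day_idx <- 0L
      for (ph in seq_along(phases_p)) {
        phase <- phases_p[ph]
        wd_done <- 0L
        while (wd_done < config$workdays_per_phase) {
          day_idx <- day_idx + 1L
          date <- all_days[day_idx]
          is_workday <- dow_index(date) < 5
          if (is_workday) {
            wd_done <- wd_done + 1L
            ws <- min(11, max(6, prof$habitual_work_start +
                                stats::rnorm(1, 0, 0.2)))
            we <- ws + 8 + stats::rnorm(1, 0, 0.3)
            lunch_h <- max(ws + 1.5, prof$habitual_lunch +
                             stats::rnorm(1, 0, 0.25))
            wfh <- stats::rbinom(1, 1, prof$wfh_probability)
            ev <- simulate_day_events(date, phase, TRUE, ws, we, wfh)
            meal <- draw_meal()
            consumed <- meal %>%
              mutate(across(c("net_carbs", "fat", "protein", "fiber"),
                            ~ .x * (1 - .data$leftover_fraction)))
            gl <- glycemic_load(consumed$net_carbs, consumed$fat,
                                consumed$protein, consumed$fiber)
            stepping_min <- window_seconds(ev, date, 0, lunch_h,
                                           c("stepping", "cycling")) / 60
            sitting_h <- window_seconds(ev, date, ws, lunch_h,
              c("sedentary", "seated_transport", "lying_primary",
                "lying_secondary")) / 3600
            day_meals <- tibble(
              time_h = c(7.5, lunch_h, 18.75),
              gl = c(stats::runif(1, 8, 20), gl, stats::runif(1, 10, 24)),
              stepping_min = c(0, stepping_min, 0),
              sitting_h = c(0, sitting_h, 0))

            true_pct <- vapply(
              list(c("sedentary", "seated_transport", "lying_primary",
                     "lying_secondary"), "standing", c("stepping", "cycling")),
              function(cl) window_seconds(ev, date, ws, we, cl), 0)
            true_pct <- 100 * true_pct / sum(true_pct)
            rep_pct <- pmin(100, pmax(0, true_pct +
              pmin(12, pmax(-12, stats::rnorm(3, 0, 5)))))
            if (sum(rep_pct) > 100) rep_pct <- 100 * rep_pct / sum(rep_pct)
            rep_pct <- round(rep_pct, 1)
            # rounding components individually can push the sum just past
            # 100; take the excess out of the largest one so the written
            # log satisfies its own validation rule
            over <- round(sum(rep_pct) - 100, 1)
            if (over > 0) {
              i <- which.max(rep_pct)
              rep_pct[i] <- round(rep_pct[i] - over, 1)
            }

            meal_l[[length(meal_l) + 1L]] <- dplyr::bind_cols(
              tibble(participant_id = pid, date = date,
                     meal_time = hms::round_hms(hms::hms(hours = lunch_h), 60)),
              meal)
            work_l[[length(work_l) + 1L]] <- tibble(
              participant_id = pid, date = date,
              work_start = hms::round_hms(hms::hms(hours = ws), 60),
              work_end = hms::round_hms(hms::hms(hours = we), 60),
              work_from_home = as.integer(wfh),
              pct_sitting = rep_pct[1],
              pct_standing = rep_pct[2],
              pct_walking = rep_pct[3],
              phase = phase)
          } else {
            ev <- simulate_day_events(date, phase, FALSE)
            day_meals <- tibble(
              time_h = c(9, 13, 19),
              gl = stats::runif(3, 8, 26),
              stepping_min = 0, sitting_h = 0)
          }
          cgm_l[[length(cgm_l) + 1L]] <- simulate_cgm_day(
            date, day_meals, prof$baseline, params,
            interval_min = config$cgm_interval) %>%
            mutate(participant_id = pid, .before = 1)
          act_l[[length(act_l) + 1L]] <- ev %>%
            mutate(participant_id = pid, .before = 1)
        }
      }
    }
    structure(list(
      cgm = dplyr::bind_rows(cgm_l),
      activity = dplyr::bind_rows(act_l),
      meals = dplyr::bind_rows(meal_l),
      work = dplyr::bind_rows(work_l),
      profiles = dplyr::bind_rows(profiles),
      params = params,
      config = config), class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d participants, %d lunch rows, %d CGM samples\n",
    nrow(x$profiles), nrow(x$meals), nrow(x$cgm)))
  invisible(x)
}

#' Write a cohort bundle to the standard CSV dialects
#'
#' Emits `cgm.csv`, `activpal_events.csv`, `food_log.csv`, `work_log.csv`,
#' `participants.csv` and `ground_truth.json` under `dir`.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cgm(bundle$cgm, file.path(dir, "cgm.csv"))
  write_activity(bundle$activity, file.path(dir, "activpal_events.csv"))
  write_meals(bundle$meals, file.path(dir, "food_log.csv"))
  write_work(bundle$work, file.path(dir, "work_log.csv"))
  readr::write_csv(bundle$profiles[c("participant_id", "bmi")],
                   file.path(dir, "participants.csv"))
  jsonlite::write_json(bundle$params[],
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
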