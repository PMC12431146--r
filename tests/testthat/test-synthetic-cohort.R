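test_that("response kernel is unimodal with unit peak at u = 1", {
  expect_equal(glucose_response_kernel(1), 1)
  expect_equal(glucose_response_kernel(0), 0)
  expect_equal(glucose_response_kernel(-2), 0)
  u <- seq(0.01, 10, by = 0.01)
  r <- glucose_response_kernel(u)
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(u[which.max(r)], 1)
  # rises before the peak, decays after it
  expect_true(all(diff(r[u < 1]) > 0))
  expect_true(all(diff(r[u > 1]) < 0))
})

test_that("meal amplitude follows the generating equation and clips at zero", {
  p <- ground_truth_params()
  expect_equal(meal_amplitude(30, 20, 2, p),
               p$gl_effect * 30 - p$stepping_effect * 20 + p$sitting_effect * 2)
  expect_equal(meal_amplitude(0, 500, 0, p), 0)
  expect_true(all(meal_amplitude(runif(50, 0, 40), runif(50, 0, 200),
                                 runif(50, 0, 5), p) >= 0))
})

test_that("parameter and config validation rejects bad values", {
  expect_error(ground_truth_params(gl_effect = -1), "finite and >= 0")
  expect_error(cohort_config(n_participants = 0), "positive")
  expect_error(cohort_config(cgm_interval = 7), "divisor")
  expect_error(cohort_config(effect_params = list(gl_effect = 1)),
               "ground_truth_params")
  expect_error(generate_cohort(list()), "cohort_config")
})

test_that("a zero-effect, zero-noise day is a flat baseline trace", {
  p <- ground_truth_params(gl_effect = 0, stepping_effect = 0,
                           sitting_effect = 0, noise_sd = 0)
  meals <- tibble::tibble(time_h = c(7.5, 12.5, 18.75), gl = c(10, 30, 15),
                          stepping_min = 0, sitting_h = 0)
  tr <- simulate_cgm_day(as.Date("2024-01-01"), meals, baseline = 95,
                         params = p)
  expect_equal(tr$glucose, rep(95, 96))
})

test_that("noise-free trace reproduces the additive meal-response model", {
  p <- ground_truth_params(noise_sd = 0)
  meals <- tibble::tibble(time_h = 12, gl = 30, stepping_min = 10,
                          sitting_h = 2)
  tr <- simulate_cgm_day(as.Date("2024-01-01"), meals, baseline = 90,
                         params = p, interval_min = 15, tau_min = 45)
  amp <- meal_amplitude(30, 10, 2, p)
  h <- as.numeric(tr$timestamp - tr$timestamp[1]) / 3600
  expected <- pmax(40, 90 + amp * glucose_response_kernel((h - 12) * 60 / 45))
  expect_equal(tr$glucose, expected)
  # the peak lands exactly one time constant after the meal
  expect_equal(h[which.max(tr$glucose)], 12.75)
  expect_equal(max(tr$glucose), 90 + amp)
})

test_that("generate_cohort is reproducible and has the declared shape", {
  b <- shared_bundle()
  b2 <- generate_cohort(cohort_config(seed = 1))
  expect_identical(b$cgm, b2$cgm)
  expect_identical(b$meals, b2$meals)
  expect_identical(b$work, b2$work)

  cfg <- b$config
  n_meals <- cfg$n_participants * cfg$n_phases * cfg$workdays_per_phase
  expect_equal(nrow(b$meals), n_meals)
  expect_equal(nrow(b$work), n_meals)
  expect_equal(nrow(b$profiles), cfg$n_participants)
  # one lunch per workday, none on weekends
  expect_true(all(dow_index(b$meals$date) < 5))
  # weekends still carry CGM samples
  expect_true(any(dow_index(as.Date(b$cgm$timestamp)) >= 5))
  # 15-min cadence: 96 samples per participant-day
  per_day <- dplyr::count(b$cgm, .data$participant_id,
                          date = as.Date(.data$timestamp))
  expect_true(all(per_day$n == 96))
  # physiologic floor
  expect_true(all(b$cgm$glucose >= 40))
  # every participant starts with Baseline and covers all three phases
  ph <- b$work %>% dplyr::group_by(participant_id) %>%
    dplyr::summarise(first = phase[which.min(date)],
                     n_ph = dplyr::n_distinct(phase))
  expect_true(all(ph$first == "Baseline"))
  expect_true(all(ph$n_ph == 3))
})

test_that("different seeds give different cohorts", {
  b <- shared_bundle()
  b3 <- generate_cohort(cohort_config(seed = 3))
  expect_false(isTRUE(all.equal(b$cgm$glucose, b3$cgm$glucose)))
})

test_that("write_cohort + read_cohort_dir round-trips the bundle", {
  b <- shared_bundle()
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("cgm.csv", "activpal_events.csv", "food_log.csv", "work_log.csv",
      "participants.csv", "ground_truth.json")))))
  src <- read_cohort_dir(dir)
  expect_equal(nrow(src$cgm), nrow(b$cgm))
  expect_equal(src$cgm$glucose, b$cgm$glucose)
  expect_equal(as.numeric(src$cgm$timestamp), as.numeric(b$cgm$timestamp))
  expect_equal(src$meals$net_carbs, b$meals$net_carbs)
  expect_equal(as.numeric(src$meals$meal_time),
               as.numeric(b$meals$meal_time))
  expect_equal(src$work$pct_standing, b$work$pct_standing)
  expect_equal(src$profiles$bmi, b$profiles$bmi)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$gl_effect, b$params$gl_effect)
})

test_that("activity events tile the day without overlap", {
  b <- shared_bundle()
  ev <- b$activity %>% dplyr::filter(participant_id == "P01") %>%
    dplyr::arrange(start)
  s <- as.numeric(ev$start)
  e <- s + ev$duration
  expect_true(all(utils::head(e, -1) <= utils::tail(s, -1) + 1e-6))
  # full coverage: total duration equals elapsed span
  expect_equal(sum(ev$duration), max(e) - min(s), tolerance = 1e-6)
})
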