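# Shared fixtures, generated once per test run and memoised. All tests that
# need a cohort use these so the suite builds the synthetic data exactly once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

shared_bundle <- function() {
  fixture("bundle", function() generate_cohort(cohort_config(seed = 1)))
}

shared_features <- function(set = "All") {
  fixture(paste0("features_", set), function()
    suppressMessages(assemble_features(shared_bundle(), set)))
}

shared_split <- function() {
  fixture("split", function()
    make_split(shared_features("All"), split_plan("ratio", 0.8, seed = 1)))
}

shared_ensemble <- function() {
  fixture("ensemble", function() {
    sp <- shared_split()
    train_ensemble(sp$train, seed = 1)
  })
}

cf_fixture <- function() {
  fixture("cf_fixture", function() {
    sp <- shared_split()
    model <- shared_ensemble()
    cons <- cf_constraints(sp$train)
    p <- predict(model, sp$test, type = "class")
    list(split = sp, model = model, cons = cons,
         hyper_idx = which(p == 1))
  })
}

# Dense-grid reference integrator: evaluates the piecewise-linear
# interpolant of (time, glucose) on a 0.1-second grid augmented with the
# sample knots and any baseline-crossing points, then integrates with the
# trapezoid rule. With those breakpoints included the trapezoid rule is
# exact for a piecewise-linear integrand, so only floating rounding
# separates it from the closed-form implementation.
dense_trapezoid <- function(time_h, value, from_h, to_h, step_s = 0.1,
                            positive_above = NULL) {
  grid <- c(seq(from_h, to_h, by = step_s / 3600),
            to_h, time_h[time_h > from_h & time_h < to_h])
  if (!is.null(positive_above)) {
    d <- value - positive_above
    cross <- which(d[-1] * d[-length(d)] < 0)
    xc <- time_h[cross] + (time_h[cross + 1] - time_h[cross]) *
      d[cross] / (d[cross] - d[cross + 1])
    grid <- c(grid, xc[xc > from_h & xc < to_h])
  }
  grid <- sort(unique(grid))
  y <- approx(time_h, value, xout = grid, rule = 1)$y
  if (!is.null(positive_above)) y <- pmax(y - positive_above, 0)
  keep <- !is.na(y)
  grid <- grid[keep]; y <- y[keep]
  sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
}
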