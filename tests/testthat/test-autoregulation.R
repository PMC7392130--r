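test_that("pressure-flow binning matches hand-computed 5-mmHg bins", {
  one <- bin_pressure_flow(make_beats(20, p = 50))
  expect_equal(one$lower_edge, 50)
  expect_equal(one$mean_pressure, 50)
  expect_equal(one$mean_flow, 20)
  expect_equal(one$count, 1L)

  b <- bin_pressure_flow(make_beats(c(10, 12, 20), p = c(41, 43, 47)))
  expect_equal(b$lower_edge, c(40, 45))
  expect_equal(b$mean_pressure, c(42, 47))
  expect_equal(b$mean_flow, c(11, 20))
  expect_equal(b$count, c(2L, 1L))
  expect_error(bin_pressure_flow(make_beats(numeric(0), p = numeric(0))),
               "empty")
})

test_that("binning conserves beat count and the global mean flow", {
  set.seed(603)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    p <- runif(n, 15, 95)
    v <- runif(n, 0, 60)
    b <- bin_pressure_flow(make_beats(v, p), bin_width = sample(c(2, 5, 10), 1))
    expect_equal(sum(b$count), n)
    expect_equal(sum(b$count * b$mean_flow) / sum(b$count), mean(v),
                 tolerance = 1e-9)
    expect_equal(sum(b$count * b$mean_pressure) / sum(b$count), mean(p),
                 tolerance = 1e-9)
    expect_true(all(diff(b$lower_edge) > 0))
  }
})

test_that("line fitting matches the closed-form normal equations", {
  col <- make_binned(c(40, 50, 60), c(10, 20, 30))
  f <- fit_line(col)
  expect_equal(f$slope, 1.0)
  expect_equal(f$intercept, -30)
  expect_equal(f$r_squared, 1)
  # flat ordinate: SST = 0, perfect fit by convention
  flat <- make_binned(c(50, 55, 60), c(20, 20, 20))
  ff <- fit_line(flat)
  expect_equal(ff$slope, 0)
  expect_equal(ff$intercept, 20)
  expect_equal(ff$r_squared, 1)
  set.seed(604)
  for (i in 1:25) {
    n <- sample(3:25, 1)
    x <- runif(n, 20, 90) + seq_len(n) * 1e-3
    y <- runif(n, 0, 40)
    got <- fit_line(make_binned(x, y))
    want <- ols_oracle(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-9)
    expect_equal(got$r_squared, want$r2, tolerance = 1e-9)
  }
  expect_error(fit_line(make_binned(c(40, 50), c(1, 2))), "3 bins")
  expect_error(fit_line(make_binned(rep(50, 3), c(1, 2, 3))), "degenerate")
})

test_that("line intersection solves both equations", {
  plateau <- structure(list(slope = 0, intercept = 20), class = "line_fit")
  ischemic <- structure(list(slope = 0.5, intercept = -5), class = "line_fit")
  pt <- intersect_lines(ischemic, plateau)
  expect_equal(unname(pt["pressure"]), 50)
  expect_equal(unname(pt["flow"]), 20)
  expect_equal(ischemic$slope * pt["pressure"] + ischemic$intercept,
               plateau$slope * pt["pressure"] + plateau$intercept,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(intersect_lines(plateau, plateau), "parallel")
})

test_that("a noise-free knee at a bin boundary is recovered exactly", {
  fit <- fit_breakpoint(exact_knee_bins())
  expect_equal(fit$breakpoint_pressure, 50, tolerance = 1e-9)
  expect_equal(fit$breakpoint_flow, 20, tolerance = 1e-9)
  expect_equal(fit$ischemic$r_squared, 1)
  expect_equal(fit$plateau$r_squared, 1)
  expect_true(fit$in_range)
  # breakpoint satisfies both line equations
  expect_equal(fit$ischemic$slope * fit$breakpoint_pressure +
                 fit$ischemic$intercept,
               fit$plateau$slope * fit$breakpoint_pressure +
                 fit$plateau$intercept,
               tolerance = 1e-9)
})

test_that("split selection equals brute-force enumeration", {
  set.seed(605)
  for (i in 1:60) {
    bins <- random_binned(sample(6:30, 1))
    want <- split_oracle(as.data.frame(bins))
    got <- tryCatch(fit_breakpoint(bins), error = function(e) e)
    if (inherits(got, "error")) {
      expect_match(conditionMessage(got), "parallel")
    } else {
      expect_equal(got$split_index, want$k)
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_equal(got$ischemic$sse + got$plateau$sse, want$sse,
                   tolerance = 1e-9)
    }
  }
})

test_that("bin input order does not change the breakpoint fit", {
  bins <- exact_knee_bins()
  rev_bins <- bins[nrow(bins):1, ]
  a <- fit_breakpoint(bins)
  b <- fit_breakpoint(rev_bins)
  expect_equal(a$breakpoint_pressure, b$breakpoint_pressure)
  expect_equal(a$split_index, b$split_index)
  expect_equal(a$score, b$score)
})

test_that("degenerate split inputs are rejected with clear errors", {
  small <- make_binned(c(20, 30, 40, 50, 60), c(5, 10, 15, 20, 20))
  expect_error(fit_breakpoint(small), "6 bins")
  # collinear data: both limbs parallel at every split
  line <- make_binned(seq(20, 75, by = 5), 0.5 * seq(20, 75, by = 5))
  expect_error(fit_breakpoint(line), "parallel")
})

test_that("ramp analysis recovers a known breakpoint from noisy beats", {
  cfg <- coro_config(seed = 909L)
  beats <- detect_beats(simulate_ramp(cfg), cfg$heart_rate)
  fit <- analyze_ramp(beats, 0, cfg$ramp_duration + 1)
  expect_lt(abs(fit$breakpoint_pressure - cfg$breakpoint_pressure), 2.5)
  expect_true(fit$in_range)
  # ischemic limb rises; plateau is the flatter line
  expect_gt(fit$ischemic$slope, 0)
  expect_lt(abs(fit$plateau$slope), abs(fit$ischemic$slope))
})

test_that("a ramp window with no sub-breakpoint beats cannot be fitted", {
  cfg <- noise_free_config()
  beats <- detect_beats(simulate_ramp(cfg), cfg$heart_rate)
  # restrict to the early ramp: pressures still above the breakpoint
  expect_error(analyze_ramp(beats, 0, 30), "bins")
  expect_error(analyze_ramp(make_beats(numeric(0), p = numeric(0)), 0, 10),
               "no beats")
})

test_that("small-sample parameter recovery stays within tolerance", {
  study <- breakpoint_recovery_study(n = 15, seed = 303)
  expect_lt(median(study$abs_error), 2.5)
  expect_gte(mean(study$in_range), 0.95)
})
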