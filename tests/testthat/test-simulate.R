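test_that("autoregulation flow model evaluates both limbs and their knot", {
  cfg <- coro_config(plateau_slope = 0, baseline_velocity = 19.1,
                     breakpoint_pressure = 49, zero_flow_pressure = 10)
  expect_equal(flow_at_pressure(80, cfg), 19.1)
  expect_equal(flow_at_pressure(29.5, cfg), 9.55)
  expect_equal(flow_at_pressure(10, cfg), 0)
  expect_equal(flow_at_pressure(0, cfg), 0)  # floored below the intercept
})

test_that("flow model is continuous at the breakpoint for any valid config", {
  set.seed(401)
  for (i in 1:25) {
    zfp <- runif(1, 0, 25)
    bp <- runif(1, zfp + 5, 60)
    cfg <- coro_config(zero_flow_pressure = zfp, breakpoint_pressure = bp,
                       ramp_start_pressure = runif(1, bp + 5, 110),
                       ramp_end_pressure = zfp + 1,
                       plateau_slope = runif(1, -0.05, 0.1),
                       baseline_velocity = runif(1, 10, 30))
    eps <- 1e-7
    expect_lt(abs(flow_at_pressure(bp - eps, cfg) -
                    flow_at_pressure(bp + eps, cfg)), 1e-5)
  }
})

test_that("intra-beat template has zero-mean pressure and unit-mean velocity", {
  cfg <- coro_config()
  dp_mean <- integrate(function(ph) beat_template(cfg, ph)$dp,
                       0, 0.35, rel.tol = 1e-12)$value +
    integrate(function(ph) beat_template(cfg, ph)$dp,
              0.35, 1, rel.tol = 1e-12)$value
  vm_mean <- integrate(function(ph) beat_template(cfg, ph)$vmult,
                       0, 0.35, rel.tol = 1e-12)$value +
    integrate(function(ph) beat_template(cfg, ph)$vmult,
              0.35, 1, rel.tol = 1e-12)$value
  expect_lt(abs(dp_mean), 1e-9)
  expect_lt(abs(vm_mean - 1), 1e-9)
  ph <- seq(0, 0.999, by = 1e-3)
  tpl <- beat_template(cfg, ph)
  expect_equal(max(tpl$dp) - min(tpl$dp), cfg$pulse_pressure, tolerance = 1e-3)
  expect_true(all(tpl$vmult > 0))
})

test_that("zero pulse pressure degenerates the template to a flat carrier", {
  cfg <- coro_config(pulse_pressure = 0)
  tpl <- beat_template(cfg, seq(0, 0.99, by = 0.01))
  expect_true(all(tpl$dp == 0))
  expect_true(all(abs(tpl$vmult - 1) < 1e-12))
})

test_that("with zero noise and zero pulse the velocity equals its envelope", {
  cfg <- noise_free_config(pulse_pressure = 0)
  rec <- simulate_bolus(cfg, duration = 60, onset = 15)
  env <- cfg$baseline_velocity * hyperemia_envelope(rec$time - 15, cfg)
  expect_lt(max(abs(rec$velocity - env)), 1e-9)
})

test_that("bolus envelope peaks at the hyperemic gain at beat resolution", {
  cfg <- noise_free_config()
  rec <- simulate_bolus(cfg, duration = 80, onset = 15)
  beats <- detect_beats(rec, cfg$heart_rate)
  base <- mean(head(beats$mean_velocity, 5))
  expect_equal(max(beats$mean_velocity) / base, cfg$hyperemic_gain,
               tolerance = 0.05 / cfg$hyperemic_gain)
  # pre-onset beats sit at baseline
  pre <- beats_in_window(beats, 0, 15)
  expect_equal(pre$mean_velocity,
               rep(cfg$baseline_velocity, nrow(pre)), tolerance = 0.005)
})

test_that("a vanishing gain leaves the bolus statistically at rest", {
  cfg <- noise_free_config(hyperemic_gain = 1 + 1e-9)
  rec <- simulate_bolus(cfg, duration = 60, onset = 15)
  beats <- detect_beats(rec, cfg$heart_rate)
  expect_equal(beats$mean_velocity,
               rep(cfg$baseline_velocity, nrow(beats)), tolerance = 0.005)
})

test_that("bolus segments too short for the transient are rejected", {
  cfg <- coro_config()
  expect_error(simulate_bolus(cfg, duration = 20, onset = 15), "too short")
})

test_that("noise-free ramp beats lie on the autoregulation curve", {
  cfg <- noise_free_config()
  rec <- simulate_ramp(cfg)
  beats <- detect_beats(rec, cfg$heart_rate)
  inner <- beats_in_window(beats, 2, cfg$ramp_duration - 2)
  pred <- flow_at_pressure(inner$mean_pressure, cfg)
  expect_lt(max(abs(inner$mean_velocity - pred)), 0.25)
  # ramp ends above the zero-flow pressure, so flow never collapses to zero
  expect_gt(min(beats$mean_velocity), 0)
})

test_that("equal seeds reproduce recordings bitwise; seeds move only noise", {
  cfg <- coro_config(seed = 31L)
  a <- simulate_ramp(cfg)
  b <- simulate_ramp(cfg)
  expect_identical(a, b)
  e1 <- generate_experiment(coro_config(seed = 1L))
  e2 <- generate_experiment(coro_config(seed = 2L))
  expect_identical(e1$annotations, e2$annotations)
  expect_false(identical(e1$velocity, e2$velocity))
})

test_that("the full protocol carries the published event schedule", {
  rec <- generate_experiment(coro_config(seed = 8L))
  kinds <- rec$annotations$kind
  expect_equal(sum(kinds == "bolus_adenosine"), 3)
  expect_equal(sum(kinds == "bolus_bradykinin"), 3)
  expect_equal(sum(kinds == "ramp_start"), 1)
  expect_equal(sum(kinds == "ramp_end"), 1)
  # concatenation conserves duration: rest + 6 boluses + gap + ramp
  expect_equal(length(rec$time) / rec$sampling_rate, 60 + 6 * 75 + 15 + 180)
  expect_true(all(diff(rec$time) > 0))
  expect_equal(max(abs(diff(rec$time) - 1 / rec$sampling_rate)), 0,
               tolerance = 1e-9)
})

test_that("long-run resting beat means recover the configured baseline", {
  cfg <- coro_config(seed = 61L)
  rec <- simulate_rest(cfg, duration = 90)
  beats <- detect_beats(rec, cfg$heart_rate)
  se <- sd(beats$mean_velocity) / sqrt(nrow(beats))
  expect_lt(abs(mean(beats$mean_velocity) - cfg$baseline_velocity), 3 * se)
})

test_that("stepwise ramp mode dwells on 5-mmHg pressure steps", {
  cfg <- noise_free_config(pulse_pressure = 0)
  rec <- simulate_ramp(cfg, mode = "step", step_size = 5, step_dwell = 20)
  # mean pressure is piecewise constant on 20 s dwells
  lvl <- rec$pressure[rec$time > 0.5 & rec$time < 19.5]
  expect_equal(max(lvl) - min(lvl), 0, tolerance = 1e-9)
  expect_equal(length(rec$time) / rec$sampling_rate,
               20 * length(seq(85, 20, by = -5)))
})
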