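test_that("baseline flow is the mean of the last five resting beats", {
  expect_equal(baseline_flow(make_beats(rep(19.1, 5))), 19.1)
  expect_equal(baseline_flow(make_beats(c(18, 19, 20, 19, 19))), 19.0)
  # with more than five beats only the final five count
  expect_equal(baseline_flow(make_beats(c(100, 18, 19, 20, 19, 19))), 19.0)
  expect_error(baseline_flow(make_beats(c(18, 19, 20, 19))), "4")
})

test_that("hyperemic flow finds the best three-successive-beat window", {
  res <- hyperemic_flow(make_beats(c(10, 30, 50, 60, 55, 20)))
  expect_equal(res$flow, 55.0)
  expect_equal(res$window, c(2, 5))  # beats 3-5 on the unit grid
  # constant series: first window wins the tie
  tie <- hyperemic_flow(make_beats(rep(42, 6)))
  expect_equal(tie$flow, 42)
  expect_equal(tie$window, c(0, 3))
  # exactly three beats: the single candidate window
  expect_equal(hyperemic_flow(make_beats(c(50, 60, 70)))$flow, 60)
  expect_error(hyperemic_flow(make_beats(c(50, 60))), "2")
})

test_that("window search equals brute-force enumeration", {
  set.seed(502)
  for (i in 1:40) {
    v <- runif(sample(3:40, 1), 5, 80)
    expect_equal(hyperemic_flow(make_beats(v))$flow,
                 best_window_oracle(v, 3)$mean)
  }
})

test_that("hyperemic pressure averages the same beats as hyperemic flow", {
  beats <- make_beats(c(10, 30, 50, 60, 55, 20), p = c(90, 80, 70, 60, 62, 85))
  hf <- hyperemic_flow(beats)
  expect_equal(hyperemic_pressure(beats, hf$window), mean(c(70, 60, 62)))
  # constant pressure trace returns that constant
  cp <- make_beats(c(10, 30, 50), p = rep(61, 3))
  expect_equal(hyperemic_pressure(cp, hyperemic_flow(cp)$window), 61)
  expect_error(hyperemic_pressure(beats, c(100, 101)), "no beats")
})

test_that("CFR and HMR are the defining ratios with guarded domains", {
  expect_equal(cfr(20.2, 57.6), 57.6 / 20.2)
  expect_equal(round(cfr(20.2, 57.6), 1), 2.9)
  expect_equal(cfr(19.1, 60.3), 60.3 / 19.1)
  expect_equal(cfr(19, 19), 1.0)
  expect_error(cfr(0, 50), "baseline")
  expect_equal(hmr(61, 60.3), 61 / 60.3)
  expect_equal(hmr(0, 50), 0)
  expect_equal(hmr(55, 55), 1)
  expect_error(hmr(61, 0), "hyperemic")
})

test_that("CFR classification follows the clinical thresholds strictly", {
  expect_equal(classify_cfr(3.3), "normal")
  expect_equal(classify_cfr(1.5), "pathological")
  expect_equal(classify_cfr(3.0), "intermediate")
  expect_equal(classify_cfr(2.0), "intermediate")
  expect_equal(classify_cfr(2.5), "intermediate")
  expect_equal(classify_cfr(3.0 + 1e-9), "normal")
  expect_error(classify_cfr(0), "positive")
  expect_error(classify_cfr(NA_real_), "positive")
})

test_that("CFR is scale-free and HMR scales inversely with velocity", {
  v_base <- 19.1
  v_hyp <- 57.3
  p <- 61
  for (c_scale in c(0.5, 2, 7.3)) {
    expect_equal(cfr(c_scale * v_base, c_scale * v_hyp), cfr(v_base, v_hyp))
    expect_equal(hmr(p, c_scale * v_hyp), hmr(p, v_hyp) / c_scale)
  }
})

test_that("a simulated bolus analysis recovers the configured gain", {
  cfg <- noise_free_config()
  beats <- detect_beats(simulate_bolus(cfg, duration = 80, onset = 15),
                        cfg$heart_rate)
  res <- analyze_bolus(beats, 15, drug = "adenosine")
  expect_equal(res$cfr, 3.0, tolerance = 0.05 / 3)
  # distal pressure at peak hyperemia drops to ~61 mmHg from MAP 89
  expect_equal(res$hyperemic_pressure, 61, tolerance = 0.02)
  expect_equal(res$hmr, res$hyperemic_pressure / res$hyperemic_flow)
  expect_equal(res$cfr, res$hyperemic_flow / res$baseline_flow)
})

test_that("noise-free replicates are deterministic and identical", {
  cfg <- noise_free_config()
  runs <- lapply(1:3, function(i) {
    beats <- detect_beats(simulate_bolus(cfg, duration = 80, onset = 15),
                          cfg$heart_rate)
    analyze_bolus(beats, 15)
  })
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[2]], runs[[3]])
})
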