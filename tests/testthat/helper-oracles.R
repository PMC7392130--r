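# Independent oracles, kept deliberately separate from the package code
# paths they check.

# Closed-form normal-equations OLS.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x)
  sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  intercept <- (sy - slope * sx) / n
  sse <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst < 1e-12) (if (sse < 1e-12) 1 else 0) else 1 - sse / sst
  list(slope = slope, intercept = intercept,
       r2 = min(max(r2, 0), 1), sse = sse)
}

# Brute-force enumeration of contiguous two-segment splits: minimal pooled
# SSE, ties by higher summed R2, then lower split index.
split_oracle <- function(bins, min_segment = 3) {
  bins <- bins[order(bins$mean_pressure), ]
  n <- nrow(bins)
  best <- NULL
  for (k in min_segment:(n - min_segment)) {
    lo <- ols_oracle(bins$mean_pressure[1:k], bins$mean_flow[1:k])
    hi <- ols_oracle(bins$mean_pressure[(k + 1):n], bins$mean_flow[(k + 1):n])
    cand <- list(k = k, sse = lo$sse + hi$sse, score = lo$r2 + hi$r2)
    if (is.null(best) ||
        cand$sse < best$sse - 1e-12 ||
        (abs(cand$sse - best$sse) <= 1e-12 && cand$score > best$score + 1e-12)) {
      best <- cand
    }
  }
  best
}

# Brute-force maximal k-consecutive-beat window mean.
best_window_oracle <- function(v, k = 3) {
  means <- vapply(seq_len(length(v) - k + 1),
                  function(i) mean(v[i:(i + k - 1)]), numeric(1))
  list(mean = max(means), index = which.max(means))
}

# Hand-built beat series (unit-length beats starting at t = 0).
make_beats <- function(v, p = rep(90, length(v))) {
  n <- length(v)
  cororeg:::new_beat_series(
    data.frame(start_time = seq_len(n) - 1, end_time = seq_len(n),
               mean_pressure = p, mean_velocity = v,
               peak_pressure = p + 20),
    data.frame(kind = character(0), onset_s = numeric(0),
               duration_s = numeric(0)))
}

# Binned pressure-flow table built directly (bypasses bin_pressure_flow).
make_binned <- function(mean_pressure, mean_flow,
                        count = rep(5L, length(mean_pressure)),
                        bin_width = 5) {
  lower <- floor(mean_pressure / bin_width) * bin_width
  structure(data.frame(lower_edge = lower, center = lower + bin_width / 2,
                       mean_pressure = mean_pressure, mean_flow = mean_flow,
                       count = count),
            class = c("binned_pf", "data.frame"))
}

# Random binned dataset: kinked two-line data with noise, occasionally pure
# noise, for split-search oracle equivalence.
random_binned <- function(n_bins) {
  p <- sort(stats::runif(n_bins, 15, 95))
  p <- p + seq_len(n_bins) * 1e-3   # guarantee distinct, ordered pressures
  if (stats::runif(1) < 0.3) {
    f <- stats::runif(n_bins, 0, 30)
  } else {
    knot <- stats::runif(1, stats::quantile(p, 0.25), stats::quantile(p, 0.75))
    s1 <- stats::runif(1, 0.2, 0.8)
    s2 <- stats::runif(1, -0.05, 0.1)
    f0 <- s1 * (knot - min(p))
    f <- ifelse(p < knot, s1 * (p - min(p)), f0 + s2 * (p - knot)) +
      stats::rnorm(n_bins, 0, stats::runif(1, 0, 2))
  }
  make_binned(p, f, count = sample(1:30, n_bins, replace = TRUE))
}

# Noise-free piecewise-linear binned curve with the knot at a bin boundary:
# plateau flow 20 above 50 mmHg, ischemic line through (10, 0) below.
exact_knee_bins <- function() {
  p <- seq(22.5, 82.5, by = 5)
  f <- ifelse(p >= 50, 20, 0.5 * (p - 10))
  make_binned(p, f)
}

noise_free_config <- function(...) {
  coro_config(beat_noise_sd_velocity = 0, beat_noise_sd_pressure = 0, ...)
}
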