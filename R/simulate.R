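#' @title Synthetic coronary waveform recordings
#' @description Internal constructor for a sampled recording of distal
#'   coronary pressure and Doppler flow velocity with event annotations.
#' @keywords internal
new_recording <- function(time, pressure, velocity, sampling_rate,
                          annotations) {
  stopifnot(length(time) == length(pressure),
            length(time) == length(velocity))
  rec <- list(
    time = time,
    pressure = pressure,
    velocity = velocity,
    sampling_rate = sampling_rate,
    annotations = annotations
  )
  class(rec) <- "coro_recording"
  rec
}

#' @export
print.coro_recording <- function(x, ...) {
  cat(sprintf(
    "<coro_recording> %.1f s at %g Hz (%d samples), %d annotation(s)\n",
    x$time[length(x$time)] - x$time[1] + 1 / x$sampling_rate,
    x$sampling_rate, length(x$time), nrow(x$annotations)))
  if (nrow(x$annotations)) {
    print(x$annotations, row.names = FALSE)
  }
  invisible(x)
}

.annotation_kinds <- c("bolus_adenosine", "bolus_bradykinin",
                       "ramp_start", "ramp_end", "rest_window")

annotation <- function(kind, onset_s, duration_s = NA_real_) {
  kind <- match.arg(kind, .annotation_kinds)
  data.frame(kind = kind, onset_s = onset_s, duration_s = duration_s,
             stringsAsFactors = FALSE)
}

# Sample grid for a segment. `t0` is the segment's start on the global
# protocol clock: cardiac phase and beat indices are computed on that
# global clock so concatenated segments share one continuous beat grid
# (no carrier discontinuity at segment boundaries).
.segment_grid <- function(config, duration, t0 = 0) {
  dt <- 1 / config$sampling_rate
  n <- round(duration * config$sampling_rate)
  time <- (seq_len(n) - 1L) * dt
  period <- 60 / config$heart_rate
  tg <- time + t0
  k0 <- floor(t0 / period + 1e-12)
  n_beats <- as.integer(floor((t0 + duration) / period + 1e-12) - k0 + 2L)
  list(time = time, n = n, period = period,
       phase = (tg %% period) / period,
       u = pmax(tg / period - k0, 0),     # beats since segment's first beat
       n_beats = n_beats)
}

# Per-sample noise trace from per-beat offsets. Piecewise constant over each
# beat with a cosine cross-fade of width `w` seconds at beat boundaries, so
# the composite pressure trace stays continuous and noise steps cannot
# masquerade as systolic upstrokes during beat detection. `u` is time in
# beats since the first beat covered by `per_beat`.
.smooth_beat_steps <- function(per_beat, u, period, w = 0.1) {
  n <- length(per_beat)
  k <- pmin(pmax(floor(u) + 1L, 1L), n)
  out <- per_beat[k]
  hw <- w / 2
  d <- (u - floor(u)) * period          # time since beat start
  i <- which(d < hw & k > 1L)
  if (length(i)) {
    a <- 0.5 * (1 - sin(pi * d[i] / w))  # weight of previous beat
    out[i] <- a * per_beat[k[i] - 1L] + (1 - a) * per_beat[k[i]]
  }
  e <- period - d                        # time to beat end
  j <- which(e < hw & k < n)
  if (length(j)) {
    b <- 0.5 * (1 - sin(pi * e[j] / w))
    out[j] <- b * per_beat[k[j] + 1L] + (1 - b) * per_beat[k[j]]
  }
  out
}

# Assemble a segment from a continuous mean-pressure trace and a continuous
# velocity envelope, adding per-beat noise and the pulsatile template.
.compose_segment <- function(config, grid, mean_p, env_v, annotations, seed) {
  withr::with_seed(seed, {
    noise_p <- stats::rnorm(grid$n_beats, 0, config$beat_noise_sd_pressure)
    noise_v <- stats::rnorm(grid$n_beats, 0, config$beat_noise_sd_velocity)
  })
  tpl <- beat_template(config, grid$phase)
  p <- mean_p + .smooth_beat_steps(noise_p, grid$u, grid$period) + tpl$dp
  v <- (env_v + .smooth_beat_steps(noise_v, grid$u, grid$period)) * tpl$vmult
  new_recording(grid$time, pmax(p, 0), pmax(v, 0),
                config$sampling_rate, annotations)
}

#' Simulate a resting recording segment
#'
#' Pulsatile pressure around the configured mean and flow velocity around the
#' configured baseline, with per-beat noise; no events beyond a covering
#' rest-window annotation.
#'
#' @param config A [coro_config()].
#' @param duration Segment duration, s.
#' @param seed Seed for this segment's noise (defaults to `config$seed`).
#' @param t0 Segment start time on the protocol clock, s (keeps the cardiac
#'   phase continuous across concatenated segments).
#' @return A `"coro_recording"`.
#' @export
simulate_rest <- function(config, duration = 60, seed = config$seed, t0 = 0) {
  validate_config(config)
  grid <- .segment_grid(config, duration, t0)
  ann <- annotation("rest_window", 0, duration)
  .compose_segment(config, grid,
                   mean_p = rep(config$mean_pressure, grid$n),
                   env_v = rep(config$baseline_velocity, grid$n),
                   annotations = ann, seed = seed)
}

#' Simulate a vasodilator bolus segment
#'
#' Flow velocity follows `baseline_velocity` times the gamma-variate
#' [hyperemia_envelope()]: unity before bolus onset, peaking at
#' `hyperemic_gain` at `hyperemia_time_to_peak` after onset and relaxing back
#' with `hyperemia_decay_tau`. Mean pressure dips by
#' `hyperemic_pressure_drop` in proportion to the envelope excursion. The
#' pre-onset interval is annotated as a rest window and the bolus as a
#' `bolus_<drug>` event.
#'
#' @param config A [coro_config()].
#' @param duration Segment duration, s; must contain the rest window plus the
#'   hyperemia transient (`onset + time_to_peak + decay_tau`).
#' @param drug `"adenosine"` or `"bradykinin"`.
#' @param onset Bolus onset time within the segment, s.
#' @param seed Seed for this segment's noise.
#' @param t0 Segment start time on the protocol clock, s.
#' @return A `"coro_recording"`.
#' @export
simulate_bolus <- function(config, duration = 75,
                           drug = c("adenosine", "bradykinin"),
                           onset = 20, seed = config$seed, t0 = 0) {
  validate_config(config)
  drug <- match.arg(drug)
  min_dur <- onset + config$hyperemia_time_to_peak + config$hyperemia_decay_tau
  if (duration < min_dur) {
    stop(sprintf(
      "duration %.1f s too short to contain the hyperemia transient (need >= %.1f s)",
      duration, min_dur))
  }
  grid <- .segment_grid(config, duration, t0)
  m <- hyperemia_envelope(grid$time - onset, config)
  env_v <- config$baseline_velocity * m
  mean_p <- config$mean_pressure -
    config$hyperemic_pressure_drop * (m - 1) / (config$hyperemic_gain - 1)
  ann <- rbind(annotation("rest_window", 0, onset),
               annotation(paste0("bolus_", drug), onset))
  .compose_segment(config, grid, mean_p, env_v, ann, seed)
}

#' Simulate a balloon-inflation pressure ramp
#'
#' Mean distal pressure declines from `ramp_start_pressure` to
#' `ramp_end_pressure` over `ramp_duration` — linearly in `"continuous"`
#' mode, or in 5-mmHg steps with a fixed dwell in `"step"` mode (mimicking
#' manual stepwise balloon inflation; the step schedule then sets the
#' duration). Each beat's velocity level is the steady-state
#' [flow_at_pressure()] response to that beat's noisy mean pressure, plus
#' per-beat velocity noise, so beats trace the plateau above the breakpoint
#' and the ischemic relation below it.
#'
#' @param config A [coro_config()].
#' @param mode `"continuous"` (default) or `"step"`.
#' @param step_size Pressure decrement per step in `"step"` mode, mmHg.
#' @param step_dwell Dwell time per step in `"step"` mode, s.
#' @param seed Seed for this segment's noise.
#' @param t0 Segment start time on the protocol clock, s.
#' @return A `"coro_recording"` annotated with `ramp_start` and `ramp_end`.
#' @export
simulate_ramp <- function(config, mode = c("continuous", "step"),
                          step_size = 5, step_dwell = 20,
                          seed = config$seed, t0 = 0) {
  validate_config(config)
  mode <- match.arg(mode)
  if (mode == "step") {
    levels <- seq(config$ramp_start_pressure, config$ramp_end_pressure,
                  by = -abs(step_size))
    if (levels[length(levels)] > config$ramp_end_pressure) {
      levels <- c(levels, config$ramp_end_pressure)
    }
    duration <- length(levels) * step_dwell
    ramp_at <- function(t) levels[pmin(floor(t / step_dwell) + 1L, length(levels))]
  } else {
    duration <- config$ramp_duration
    slope <- (config$ramp_end_pressure - config$ramp_start_pressure) / duration
    ramp_at <- function(t) config$ramp_start_pressure + slope * t
  }
  grid <- .segment_grid(config, duration, t0)
  withr::with_seed(seed, {
    noise_p <- stats::rnorm(grid$n_beats, 0, config$beat_noise_sd_pressure)
    noise_v <- stats::rnorm(grid$n_beats, 0, config$beat_noise_sd_velocity)
  })
  # local time of each covered beat's midpoint, clamped into the ramp
  k0 <- floor(t0 / grid$period + 1e-12)
  beat_mid <- (k0 + seq_len(grid$n_beats) - 0.5) * grid$period - t0
  beat_p <- pmax(ramp_at(pmin(pmax(beat_mid, 0), duration)) + noise_p, 0)
  beat_v <- pmax(flow_at_pressure(beat_p, config) + noise_v, 0)

  tpl <- beat_template(config, grid$phase)
  p <- ramp_at(grid$time) +
    .smooth_beat_steps(noise_p, grid$u, grid$period) + tpl$dp
  v <- .smooth_beat_steps(beat_v, grid$u, grid$period) * tpl$vmult
  ann <- rbind(annotation("ramp_start", 0),
               annotation("ramp_end", duration))
  new_recording(grid$time, pmax(p, 0), pmax(v, 0),
                config$sampling_rate, ann)
}

#' Concatenate recordings end to end
#'
#' @param ... `"coro_recording"` objects sharing one sampling rate, or a
#'   single list of them.
#' @return A single `"coro_recording"` with time-shifted annotations.
#' @export
concat_recordings <- function(...) {
  recs <- list(...)
  if (length(recs) == 1 && is.list(recs[[1]]) &&
      !inherits(recs[[1]], "coro_recording")) {
    recs <- recs[[1]]
  }
  stopifnot(length(recs) >= 1,
            all(vapply(recs, inherits, logical(1), "coro_recording")))
  fs <- recs[[1]]$sampling_rate
  stopifnot(all(vapply(recs, function(r) r$sampling_rate == fs, logical(1))))
  dt <- 1 / fs
  offset <- 0
  time <- pressure <- velocity <- anns <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    time[[i]] <- r$time + offset
    pressure[[i]] <- r$pressure
    velocity[[i]] <- r$velocity
    a <- r$annotations
    a$onset_s <- a$onset_s + offset
    anns[[i]] <- a
    offset <- offset + length(r$time) * dt
  }
  new_recording(unlist(time), unlist(pressure), unlist(velocity), fs,
                do.call(rbind, anns))
}

#' Generate a full synthetic coronary protocol
#'
#' Reproduces the experimental protocol as one annotated recording: an
#' initial rest period, three adenosine boluses, three bradykinin boluses
#' (each bolus segment opens with a return-to-baseline rest window), a short
#' rest, and finally a balloon pressure ramp crossing the autoregulatory
#' breakpoint. The cardiac phase runs continuously across segments. The
#' event schedule is fixed by the segment durations; only the noise
#' realizations depend on the seed, which is derived per segment from
#' `config$seed`.
#'
#' @param config A [coro_config()].
#' @param rest_duration Initial rest duration, s.
#' @param bolus_duration Duration of each bolus segment, s.
#' @param bolus_onset Bolus onset within its segment, s.
#' @param n_replicates Boluses per drug.
#' @return A `"coro_recording"` covering the whole protocol.
#' @export
#' @examples
#' rec <- generate_experiment(coro_config(seed = 7))
#' table(rec$annotations$kind)
generate_experiment <- function(config, rest_duration = 60,
                                bolus_duration = 75, bolus_onset = 20,
                                n_replicates = 3) {
  validate_config(config)
  seg_seed <- function(i) as.integer((config$seed + 131L * i) %% 2147483629L)
  t0 <- 0
  segs <- list(simulate_rest(config, rest_duration, seed = seg_seed(0L),
                             t0 = t0))
  t0 <- t0 + rest_duration
  i <- 1L
  for (drug in c("adenosine", "bradykinin")) {
    for (rep in seq_len(n_replicates)) {
      segs <- c(segs, list(simulate_bolus(
        config, duration = bolus_duration, drug = drug,
        onset = bolus_onset, seed = seg_seed(i), t0 = t0)))
      t0 <- t0 + bolus_duration
      i <- i + 1L
    }
  }
  segs <- c(segs, list(simulate_rest(config, 15, seed = seg_seed(i), t0 = t0)))
  t0 <- t0 + 15
  segs <- c(segs, list(simulate_ramp(config, seed = seg_seed(i + 1L), t0 = t0)))
  concat_recordings(segs)
}
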