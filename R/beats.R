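#' Beat series constructor
#'
#' A beat series is a data frame with one row per cardiac cycle
#' (`start_time`, `end_time`, `mean_pressure`, `mean_velocity`,
#' `peak_pressure`), ordered and non-overlapping, carrying the source
#' recording's annotations as an attribute.
#'
#' @keywords internal
new_beat_series <- function(beats, annotations) {
  stopifnot(is.data.frame(beats))
  if (nrow(beats) > 1) {
    stopifnot(all(diff(beats$start_time) > 0),
              all(beats$end_time[-nrow(beats)] <= beats$start_time[-1] + 1e-9))
  }
  structure(beats,
            annotations = annotations,
            class = c("beat_series", "data.frame"))
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beat(s)\n", nrow(x)))
  NextMethod()
}

#' Annotations carried by a beat series or recording
#' @param x A `"beat_series"` or `"coro_recording"`.
#' @return The annotation data frame (kind, onset_s, duration_s).
#' @export
annotations <- function(x) {
  if (inherits(x, "coro_recording")) return(x$annotations)
  attr(x, "annotations")
}

#' Detect cardiac beats from the pressure waveform
#'
#' Segments a recording into foot-to-foot cardiac cycles using the pressure
#' channel (pressure pulsatility persists during balloon inflation while
#' velocity collapses, so pressure is the reliable timing signal). Systolic
#' upstrokes are located where the pressure derivative exceeds 40% of its
#' maximum, separated by a refractory period of `0.6 * (60 / expected_rate)`
#' seconds to avoid dicrotic-notch double counting; each beat onset is the
#' diastolic foot, the pressure minimum in the half-cycle preceding the
#' upstroke. Each beat spans foot to foot and is reduced to its mean
#' pressure, mean velocity and peak pressure.
#'
#' @param recording A `"coro_recording"` with a uniform time grid.
#' @param expected_rate Approximate heart rate, beats/min, in `[30, 250]`.
#' @return A `"beat_series"`; empty (zero rows) when the trace carries no
#'   pulsatile feet, e.g. constant pressure.
#' @export
detect_beats <- function(recording, expected_rate = 85) {
  stopifnot(inherits(recording, "coro_recording"))
  if (length(recording$time) == 0) stop("empty recording")
  if (expected_rate < 30 || expected_rate > 250) {
    stop("expected_rate must lie in [30, 250] beats/min")
  }
  dt <- 1 / recording$sampling_rate
  steps <- diff(recording$time)
  if (length(steps) && max(abs(steps - dt)) > 1e-6) {
    stop("non-uniform sampling grid")
  }
  p <- recording$pressure
  v <- recording$velocity
  empty <- new_beat_series(
    data.frame(start_time = numeric(0), end_time = numeric(0),
               mean_pressure = numeric(0), mean_velocity = numeric(0),
               peak_pressure = numeric(0)),
    recording$annotations)
  if (length(p) < 3 || (max(p) - min(p)) < 0.5) return(empty)

  period <- 60 / expected_rate
  refractory <- 0.6 * period

  # Slope over a ~40 ms central-difference window: wide enough that an
  # isolated step artifact (e.g. a segment seam in a stitched recording)
  # cannot rival a genuine systolic upstroke, narrow enough to keep the
  # upstroke sharp. Threshold at 40% of a high quantile rather than the
  # absolute maximum for the same reason.
  half <- max(1L, as.integer(round(0.02 / dt)))
  n <- length(p)
  if (n < 2L * half + 1L) return(empty)
  idx <- (half + 1L):(n - half)
  dp <- rep(0, n)
  dp[idx] <- (p[idx + half] - p[idx - half]) / (2 * half * dt)
  thr <- 0.4 * stats::quantile(dp, 0.995, names = FALSE)
  if (thr <= 0) return(empty)

  above <- dp > thr
  starts <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(starts)) return(empty)

  # enforce refractory between accepted upstrokes
  accepted <- starts[1]
  last_t <- recording$time[starts[1]]
  for (s in starts[-1]) {
    t_s <- recording$time[s]
    if (t_s - last_t >= refractory) {
      accepted <- c(accepted, s)
      last_t <- t_s
    }
  }

  half_win <- as.integer(round(0.5 * period / dt))
  feet <- vapply(accepted, function(i) {
    j0 <- max(1L, as.integer(i) - half_win)
    j0 - 1L + which.min(p[j0:i])
  }, integer(1))
  feet <- sort(unique(feet))
  if (length(feet) < 2) return(empty)

  cp <- cumsum(p)
  cv <- cumsum(v)
  seg_mean <- function(cs, a, b) {  # mean over samples a..(b-1)
    (cs[b - 1L] - if (a > 1L) cs[a - 1L] else 0) / (b - a)
  }
  nb <- length(feet) - 1L
  beats <- data.frame(
    start_time = recording$time[feet[-length(feet)]],
    end_time = recording$time[feet[-1]],
    mean_pressure = vapply(seq_len(nb), function(k)
      seg_mean(cp, feet[k], feet[k + 1L]), numeric(1)),
    mean_velocity = vapply(seq_len(nb), function(k)
      seg_mean(cv, feet[k], feet[k + 1L]), numeric(1)),
    peak_pressure = vapply(seq_len(nb), function(k)
      max(p[feet[k]:(feet[k + 1L] - 1L)]), numeric(1))
  )
  new_beat_series(beats, recording$annotations)
}

#' Select beats wholly contained in a time window
#'
#' A beat belongs to the window when it starts at or after `start`, ends at
#' or before `end`, and starts strictly before `end` (half-open on the beat
#' start: a beat ending exactly at `end` is kept, one starting at `end` is
#' not).
#'
#' @param series A `"beat_series"`.
#' @param start,end Window bounds, s, with `start < end`.
#' @return The contained sub-series, order preserved (possibly empty).
#' @export
beats_in_window <- function(series, start, end) {
  stopifnot(inherits(series, "beat_series"), start < end)
  eps <- 1e-9
  keep <- series$start_time >= start - eps &
    series$end_time <= end + eps &
    series$start_time < end - eps
  new_beat_series(as.data.frame(series)[keep, , drop = FALSE],
                  annotations(series))
}

#' Export a beat series as CSV
#'
#' Writes `start_s,end_s,mean_pressure_mmhg,mean_velocity_cm_s`, one row per
#' beat.
#'
#' @param series A `"beat_series"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  out <- data.frame(start_s = series$start_time,
                    end_s = series$end_time,
                    mean_pressure_mmhg = series$mean_pressure,
                    mean_velocity_cm_s = series$mean_velocity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
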