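#' Baseline flow from resting beats
#'
#' Mean flow velocity over the final 5 successive beats of the rest window —
#' the beats closest to the upcoming event, where drift relative to the
#' measurement is smallest.
#'
#' @param rest_beats A `"beat_series"` of resting beats (>= 5).
#' @param n_beats Number of successive resting beats to average.
#' @return Baseline flow velocity, cm/s.
#' @export
baseline_flow <- function(rest_beats, n_beats = 5) {
  stopifnot(inherits(rest_beats, "beat_series"))
  if (nrow(rest_beats) < n_beats) {
    stop(sprintf("baseline flow needs %d resting beats, got %d",
                 n_beats, nrow(rest_beats)))
  }
  mean(utils::tail(rest_beats$mean_velocity, n_beats))
}

#' Hyperemic flow: best 3-successive-beat window
#'
#' Slides a window of `n_beats` consecutive beats over the post-bolus series
#' and returns the maximal window mean of beat velocities — the mean of the
#' three successive beats with the highest flow at maximal vasodilation.
#' Ties go to the earliest window.
#'
#' @param post_bolus_beats A `"beat_series"` after bolus onset (>= 3 beats).
#' @param n_beats Window length in beats.
#' @return A list with `flow` (cm/s) and `window` (`c(start_s, end_s)` of the
#'   selected beats).
#' @export
hyperemic_flow <- function(post_bolus_beats, n_beats = 3) {
  stopifnot(inherits(post_bolus_beats, "beat_series"))
  nb <- nrow(post_bolus_beats)
  if (nb < n_beats) {
    stop(sprintf("hyperemic flow needs %d post-bolus beats, got %d",
                 n_beats, nb))
  }
  v <- post_bolus_beats$mean_velocity
  csum <- c(0, cumsum(v))
  means <- (csum[(n_beats + 1):(nb + 1)] - csum[1:(nb - n_beats + 1)]) / n_beats
  i <- which.max(means)  # which.max returns the first maximum: earliest tie
  list(flow = means[i],
       window = c(post_bolus_beats$start_time[i],
                  post_bolus_beats$end_time[i + n_beats - 1]))
}

#' Coronary pressure at peak hyperemia
#'
#' Mean of beat mean pressures over the same beat window that defined the
#' hyperemic flow.
#'
#' @param post_bolus_beats The `"beat_series"` passed to [hyperemic_flow()].
#' @param window The `window` element returned by [hyperemic_flow()].
#' @return Hyperemic coronary pressure, mmHg.
#' @export
hyperemic_pressure <- function(post_bolus_beats, window) {
  stopifnot(inherits(post_bolus_beats, "beat_series"), length(window) == 2)
  sel <- beats_in_window(post_bolus_beats, window[1] - 1e-9, window[2] + 1e-9)
  if (nrow(sel) == 0) stop("window matches no beats")
  mean(sel$mean_pressure)
}

#' Coronary flow reserve
#'
#' Ratio of hyperemic to baseline flow velocity (velocity is the flow
#' surrogate: flow and velocity changes are proportional in a vessel of
#' fixed cross-section).
#'
#' @param baseline Baseline flow, cm/s (> 0).
#' @param hyperemic Hyperemic flow, cm/s.
#' @return Dimensionless CFR.
#' @export
#' @examples
#' cfr(20.2, 57.6)
cfr <- function(baseline, hyperemic) {
  if (baseline <= 0) stop("baseline flow must be > 0")
  hyperemic / baseline
}

#' Hyperemic microvascular resistance
#'
#' Coronary pressure divided by flow velocity at maximal vasodilation, in
#' mmHg/(cm/s); an index of microvascular function that, unlike CFR, is not
#' confounded by the resting flow level.
#'
#' @param pressure Hyperemic coronary pressure, mmHg.
#' @param hyperemic Hyperemic flow, cm/s (> 0).
#' @return HMR, mmHg/(cm/s).
#' @export
hmr <- function(pressure, hyperemic) {
  if (hyperemic <= 0) stop("hyperemic flow must be > 0")
  pressure / hyperemic
}

#' Classify a coronary flow reserve value
#'
#' Clinical thresholds: CFR above 3.0 is normal, below 2.0 pathological;
#' values in `[2.0, 3.0]` (boundaries included) are intermediate.
#'
#' @param x CFR value (> 0).
#' @return `"normal"`, `"intermediate"` or `"pathological"`.
#' @export
classify_cfr <- function(x) {
  if (!is.finite(x) || x <= 0) stop("CFR must be a positive number")
  if (x > 3.0) "normal" else if (x < 2.0) "pathological" else "intermediate"
}

#' Analyze one vasodilator bolus
#'
#' Composes the beat-selection rules into the full index set for one bolus:
#' baseline flow from the last 5 beats before onset, hyperemic flow and
#' pressure from the best 3-beat window in a post-onset search window
#' (default 60 s, truncated at the next annotated event so measurements
#' never overlap), then CFR, HMR and the CFR classification.
#'
#' @param series A `"beat_series"` covering the bolus and its preceding rest.
#' @param bolus_onset Bolus onset time, s.
#' @param drug `"adenosine"` or `"bradykinin"`.
#' @param search_window Length of the post-onset search window, s.
#' @param next_event_onset Onset of the next annotated event, s (`Inf` if
#'   none); caps the search window.
#' @return A list of class `"hyperemia_result"`: `drug`, `baseline_flow`,
#'   `hyperemic_flow`, `hyperemic_pressure`, `cfr`, `hmr`, `classification`,
#'   and the selected `window`.
#' @export
analyze_bolus <- function(series, bolus_onset,
                          drug = c("adenosine", "bradykinin"),
                          search_window = 60, next_event_onset = Inf) {
  drug <- match.arg(drug)
  stopifnot(inherits(series, "beat_series"))
  rest <- beats_in_window(series, -Inf, bolus_onset)
  base <- baseline_flow(rest)
  hi <- min(bolus_onset + search_window, next_event_onset)
  post <- beats_in_window(series, bolus_onset, hi)
  hf <- hyperemic_flow(post)
  hp <- hyperemic_pressure(post, hf$window)
  ratio <- cfr(base, hf$flow)
  structure(list(
    drug = drug,
    baseline_flow = base,
    hyperemic_flow = hf$flow,
    hyperemic_pressure = hp,
    cfr = ratio,
    hmr = hmr(hp, hf$flow),
    classification = classify_cfr(ratio),
    window = hf$window
  ), class = "hyperemia_result")
}

#' @export
print.hyperemia_result <- function(x, ...) {
  cat(sprintf(
    "<hyperemia_result> %s: baseline %.1f cm/s, hyperemic %.1f cm/s @ %.0f mmHg\n  CFR %.2f (%s), HMR %.2f mmHg/(cm/s)\n",
    x$drug, x$baseline_flow, x$hyperemic_flow, x$hyperemic_pressure,
    x$cfr, x$classification, x$hmr))
  invisible(x)
}
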