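#' Write a recording to CSV plus a JSON annotation sidecar
#'
#' The CSV carries the sampled signals with header
#' `time_s,pressure_mmhg,velocity_cm_s`; the sidecar holds
#' `{"events": [{"kind", "onset_s", "duration_s"}, ...]}`.
#'
#' @param recording A `"coro_recording"`.
#' @param csv_path Output path for the signal CSV.
#' @param annotation_path Output path for the JSON sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_recording <- function(recording, csv_path, annotation_path) {
  stopifnot(inherits(recording, "coro_recording"))
  df <- data.frame(time_s = recording$time,
                   pressure_mmhg = recording$pressure,
                   velocity_cm_s = recording$velocity)
  utils::write.csv(df, csv_path, row.names = FALSE)
  ev <- recording$annotations
  jsonlite::write_json(
    list(events = ev, sampling_rate_hz = recording$sampling_rate),
    annotation_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(csv_path)
}

#' Read a recording from CSV plus its JSON annotation sidecar
#'
#' Validates the schema (required columns), the uniformity of the time grid,
#' signal non-negativity, and that every annotation onset lies within the
#' recorded time span.
#'
#' @param csv_path Signal CSV with header `time_s,pressure_mmhg,velocity_cm_s`.
#' @param annotation_path JSON sidecar written by [write_recording()].
#' @return A `"coro_recording"`.
#' @export
read_recording <- function(csv_path, annotation_path) {
  df <- utils::read.csv(csv_path)
  required <- c("time_s", "pressure_mmhg", "velocity_cm_s")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("recording CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) < 2) stop("recording holds fewer than 2 samples")
  steps <- diff(df$time_s)
  dt <- stats::median(steps)
  if (dt <= 0 || max(abs(steps - dt)) > 1e-6) {
    stop("non-uniform time grid in recording CSV")
  }
  if (any(df$pressure_mmhg < 0) || any(df$velocity_cm_s < 0)) {
    stop("negative pressure or velocity sample in recording")
  }
  side <- jsonlite::read_json(annotation_path, simplifyVector = TRUE)
  ev <- side$events
  if (is.null(ev) || length(ev) == 0) {
    ev <- data.frame(kind = character(0), onset_s = numeric(0),
                     duration_s = numeric(0))
  }
  ev <- as.data.frame(ev)
  if (!all(c("kind", "onset_s") %in% names(ev))) {
    stop("annotation sidecar events need 'kind' and 'onset_s' fields")
  }
  if (is.null(ev$duration_s)) ev$duration_s <- NA_real_
  bad_kind <- setdiff(ev$kind, .annotation_kinds)
  if (length(bad_kind)) {
    stop("unknown annotation kind(s): ", paste(bad_kind, collapse = ", "))
  }
  t0 <- df$time_s[1]
  t1 <- df$time_s[nrow(df)] + dt  # grid covers [t, t + dt) per sample
  if (any(ev$onset_s < t0 - 1e-9 | ev$onset_s > t1 + 1e-9)) {
    stop("annotation onset outside the recorded time span")
  }
  fs <- side$sampling_rate_hz
  if (is.null(fs)) fs <- 1 / dt
  new_recording(df$time_s, df$pressure_mmhg, df$velocity_cm_s, fs,
                ev[, c("kind", "onset_s", "duration_s")])
}
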