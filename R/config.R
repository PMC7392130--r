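#' Simulation configuration for a synthetic coronary experiment
#'
#' Builds the full parameterization of a synthetic intracoronary
#' pressure/flow-velocity experiment: heart rate and pulsatility of the
#' pressure carrier, the resting flow-velocity level, the vasodilator
#' hyperemia transient, the autoregulation curve (plateau, breakpoint,
#' ischemic limb), the balloon pressure ramp, and the per-beat noise model.
#'
#' Defaults are calibrated to a healthy closed-chest porcine preparation:
#' heart rate 85 beats/min, mean distal coronary pressure 89 mmHg, baseline
#' flow velocity 19.1 cm/s, a vasodilator bolus that triples flow with a
#' distal pressure dip to about 61 mmHg at peak hyperemia, and a lower
#' autoregulatory breakpoint at 49 mmHg. The ischemic limb passes through a
#' zero-flow pressure of 10 mmHg; the plateau has a slight positive slope
#' (0.02 (cm/s)/mmHg) so autoregulation is near-perfect but not exact.
#'
#' @param heart_rate Heart rate, beats/min.
#' @param mean_pressure Mean distal coronary pressure at rest, mmHg.
#' @param pulse_pressure Peak-to-trough pulsatile pressure amplitude, mmHg.
#' @param baseline_velocity Resting mean flow velocity, cm/s.
#' @param hyperemic_gain Peak hyperemic flow as a multiple of baseline (> 1).
#' @param hyperemia_time_to_peak Time from bolus onset to peak hyperemia, s.
#' @param hyperemia_decay_tau Time constant of the hyperemia decay tail, s.
#' @param hyperemic_pressure_drop Mean-pressure dip at peak hyperemia, mmHg.
#' @param breakpoint_pressure Lower autoregulatory breakpoint, mmHg.
#' @param zero_flow_pressure Pressure-axis intercept of the ischemic limb,
#'   mmHg (flow extrapolates to zero here).
#' @param plateau_slope Slope of the autoregulatory plateau, (cm/s)/mmHg.
#' @param ramp_start_pressure Mean pressure at the start of the balloon ramp,
#'   mmHg.
#' @param ramp_end_pressure Mean pressure at the end of the ramp, mmHg; must
#'   lie below the breakpoint so both limbs are observable.
#' @param ramp_duration Duration of the ramp, s.
#' @param beat_noise_sd_velocity SD of per-beat Gaussian noise on beat-mean
#'   velocity, cm/s.
#' @param beat_noise_sd_pressure SD of per-beat Gaussian noise on beat-mean
#'   pressure, mmHg.
#' @param sampling_rate Sampling rate of the synthetic recording, Hz.
#' @param seed Integer seed; all randomness in the generators flows from it.
#'
#' @return A validated list of class `"coro_config"`.
#' @seealso [generate_experiment()], [simulate_ramp()], [simulate_bolus()]
#' @export
#' @examples
#' cfg <- coro_config()
#' cfg$breakpoint_pressure
coro_config <- function(heart_rate = 85,
                        mean_pressure = 89,
                        pulse_pressure = 40,
                        baseline_velocity = 19.1,
                        hyperemic_gain = 3.0,
                        hyperemia_time_to_peak = 8,
                        hyperemia_decay_tau = 15,
                        hyperemic_pressure_drop = 28,
                        breakpoint_pressure = 49,
                        zero_flow_pressure = 10,
                        plateau_slope = 0.02,
                        ramp_start_pressure = 85,
                        ramp_end_pressure = 20,
                        ramp_duration = 180,
                        beat_noise_sd_velocity = 1.5,
                        beat_noise_sd_pressure = 2,
                        sampling_rate = 250,
                        seed = 1L) {
  cfg <- list(
    heart_rate = heart_rate,
    mean_pressure = mean_pressure,
    pulse_pressure = pulse_pressure,
    baseline_velocity = baseline_velocity,
    hyperemic_gain = hyperemic_gain,
    hyperemia_time_to_peak = hyperemia_time_to_peak,
    hyperemia_decay_tau = hyperemia_decay_tau,
    hyperemic_pressure_drop = hyperemic_pressure_drop,
    breakpoint_pressure = breakpoint_pressure,
    zero_flow_pressure = zero_flow_pressure,
    plateau_slope = plateau_slope,
    ramp_start_pressure = ramp_start_pressure,
    ramp_end_pressure = ramp_end_pressure,
    ramp_duration = ramp_duration,
    beat_noise_sd_velocity = beat_noise_sd_velocity,
    beat_noise_sd_pressure = beat_noise_sd_pressure,
    sampling_rate = sampling_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "coro_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks the physiological and structural invariants of a [coro_config()]:
#' positive rates, non-negative pressures and noise SDs, a hyperemic gain
#' above 1, and the ordering zero-flow pressure < breakpoint < ramp start
#' with the ramp end below the breakpoint (so a ramp crosses the breakpoint
#' and both limbs of the autoregulation curve are observable).
#'
#' @param cfg A `"coro_config"` object.
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "coro_config"))
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric configuration fields: ",
         paste(names(cfg)[!num], collapse = ", "))
  }
  if (cfg$heart_rate <= 0) stop("heart_rate must be > 0")
  if (cfg$sampling_rate < 50) stop("sampling_rate must be >= 50 Hz")
  pr <- c("mean_pressure", "pulse_pressure", "hyperemic_pressure_drop",
          "breakpoint_pressure", "zero_flow_pressure",
          "ramp_start_pressure", "ramp_end_pressure")
  bad <- pr[vapply(pr, function(f) cfg[[f]] < 0, logical(1))]
  if (length(bad)) stop("negative pressure parameter(s): ",
                        paste(bad, collapse = ", "))
  if (!(cfg$zero_flow_pressure < cfg$breakpoint_pressure)) {
    stop("zero_flow_pressure must lie below breakpoint_pressure")
  }
  if (!(cfg$breakpoint_pressure < cfg$ramp_start_pressure)) {
    stop("breakpoint_pressure must lie below ramp_start_pressure")
  }
  if (!(cfg$ramp_end_pressure < cfg$breakpoint_pressure)) {
    stop("ramp_end_pressure must lie below breakpoint_pressure ",
         "(the ramp must cross the breakpoint)")
  }
  if (cfg$hyperemic_gain <= 1) stop("hyperemic_gain must be > 1")
  if (cfg$beat_noise_sd_velocity < 0 || cfg$beat_noise_sd_pressure < 0) {
    stop("noise SDs must be >= 0")
  }
  if (cfg$ramp_duration <= 0) stop("ramp_duration must be > 0")
  if (cfg$baseline_velocity <= 0) stop("baseline_velocity must be > 0")
  cfg
}

#' @export
print.coro_config <- function(x, ...) {
  cat("<coro_config>\n")
  cat(sprintf("  HR %g bpm, MAP %g mmHg (pulse %g), baseline velocity %g cm/s\n",
              x$heart_rate, x$mean_pressure, x$pulse_pressure,
              x$baseline_velocity))
  cat(sprintf("  hyperemia: gain %g, peak at %g s, decay tau %g s, dP %g mmHg\n",
              x$hyperemic_gain, x$hyperemia_time_to_peak,
              x$hyperemia_decay_tau, x$hyperemic_pressure_drop))
  cat(sprintf("  autoregulation: breakpoint %g mmHg, zero-flow %g mmHg, plateau slope %g\n",
              x$breakpoint_pressure, x$zero_flow_pressure, x$plateau_slope))
  cat(sprintf("  ramp: %g -> %g mmHg over %g s\n",
              x$ramp_start_pressure, x$ramp_end_pressure, x$ramp_duration))
  cat(sprintf("  noise SD: velocity %g cm/s, pressure %g mmHg; fs %g Hz; seed %d\n",
              x$beat_noise_sd_velocity, x$beat_noise_sd_pressure,
              x$sampling_rate, x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' @param cfg A `"coro_config"` object.
#' @param path File path of the JSON configuration.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a validated `"coro_config"`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "coro_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(coro_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "))
  }
  do.call(coro_config, raw)
}
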