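#' Steady-state autoregulation pressure-flow model
#'
#' Two-limb piecewise-linear model of steady-state coronary flow velocity as
#' a function of mean perfusion pressure. Above the breakpoint the flow lies
#' on the autoregulatory plateau, a line of slope `plateau_slope` anchored so
#' that flow equals `baseline_velocity` at `ramp_start_pressure`. Below the
#' breakpoint flow is pressure-dependent (the ischemic relation): a line
#' through the zero-flow pressure and the plateau value at the breakpoint,
#' which makes the model continuous at the knot. Flow is floored at zero.
#'
#' @param mean_pressure Mean perfusion pressure(s), mmHg; vectorized.
#' @param config A [coro_config()].
#' @return Flow velocity in cm/s, same length as `mean_pressure`.
#' @export
#' @examples
#' cfg <- coro_config(plateau_slope = 0)
#' flow_at_pressure(c(80, 49, 10), cfg)
flow_at_pressure <- function(mean_pressure, config) {
  stopifnot(all(mean_pressure >= -1e-12))
  bp <- config$breakpoint_pressure
  zfp <- config$zero_flow_pressure
  f_plateau <- function(p) {
    config$baseline_velocity + config$plateau_slope * (p - config$ramp_start_pressure)
  }
  f_knee <- f_plateau(bp)
  isch_slope <- f_knee / (bp - zfp)
  f <- ifelse(mean_pressure >= bp,
              f_plateau(mean_pressure),
              isch_slope * (mean_pressure - zfp))
  pmax(f, 0)
}

# Intra-beat waveform shape constants: systole occupies 35% of the cycle;
# the pressure wave is a half-sinusoid stretched so end-systole sits at
# sin(0.8*pi), followed by an exponential diastolic decay (time constant
# 0.18 cycle) pulled linearly to zero at end-diastole so the template is
# continuous and periodic. Velocity dips during systole and peaks in
# diastole (coronary flow is diastolic-dominant).
.SYS_FRAC <- 0.35
.SYS_STRETCH <- 1.25
.DIA_TAU <- 0.18
.VEL_SWING <- 0.5

# Raw (unnormalized) pressure shape on phase [0,1): >= 0, zero at both ends,
# unit peak. Exact mean has closed form (used to center the template).
.press_shape <- function(phase) {
  f <- .SYS_FRAC
  e_sys <- sin(pi / .SYS_STRETCH)
  decay_end <- exp(-(1 - f) / .DIA_TAU)
  sys <- phase < f
  out <- numeric(length(phase))
  out[sys] <- sin(pi * phase[sys] / (f * .SYS_STRETCH))
  ph_d <- phase[!sys]
  out[!sys] <- e_sys * (exp(-(ph_d - f) / .DIA_TAU) -
                          decay_end * (ph_d - f) / (1 - f))
  out
}

.press_shape_mean <- function() {
  f <- .SYS_FRAC
  e_sys <- sin(pi / .SYS_STRETCH)
  decay_end <- exp(-(1 - f) / .DIA_TAU)
  i_sys <- (.SYS_STRETCH * f / pi) * (1 - cos(pi / .SYS_STRETCH))
  i_dia <- e_sys * (.DIA_TAU * (1 - decay_end) - decay_end * (1 - f) / 2)
  i_sys + i_dia
}

# Raw velocity modulation: -sin hump in systole, +sin hump in diastole.
.vel_shape <- function(phase) {
  f <- .SYS_FRAC
  sys <- phase < f
  out <- numeric(length(phase))
  out[sys] <- -sin(pi * phase[sys] / f)
  out[!sys] <- sin(pi * (phase[!sys] - f) / (1 - f))
  out
}

.vel_shape_mean <- function() (2 / pi) * (1 - 2 * .SYS_FRAC)

#' Intra-beat pressure and velocity template
#'
#' Periodic waveform shapes evaluated at a cardiac-cycle phase. The pressure
#' component is a zero-mean deviation (mmHg) whose peak-to-trough amplitude
#' equals the configured pulse pressure: a half-sinusoid systole (35% of the
#' cycle) followed by an exponential diastolic decay. The velocity component
#' is a strictly positive multiplier with exact unit mean over the cycle,
#' weighted toward diastole. Downstream analyses consume beat means only, so
#' the template's shape affects pulsatility but not beat-level results.
#'
#' @param config A [coro_config()].
#' @param phase Phase of the cardiac cycle in `[0, 1)`; vectorized.
#' @return A list with components `dp` (pressure deviation, mmHg) and
#'   `vmult` (dimensionless velocity multiplier), each aligned with `phase`.
#' @export
beat_template <- function(config, phase) {
  stopifnot(all(phase >= 0), all(phase < 1))
  dp <- config$pulse_pressure * (.press_shape(phase) - .press_shape_mean())
  # velocity pulsatility scales with pressure pulsatility (both stem from
  # the same ejection cycle); a non-pulsatile carrier has a flat multiplier
  swing <- .VEL_SWING * min(config$pulse_pressure / 40, 1.2)
  vmult <- (1 + swing * .vel_shape(phase)) / (1 + swing * .vel_shape_mean())
  list(dp = dp, vmult = vmult)
}

#' Hyperemia envelope after a vasodilator bolus
#'
#' Gamma-variate flow multiplier: 1 before onset, rising to `hyperemic_gain`
#' at `hyperemia_time_to_peak` after onset, then relaxing back to 1 with an
#' asymptotic time constant `hyperemia_decay_tau`. The gamma-variate shape
#' exponent is `time_to_peak / decay_tau`, which ties the tail decay rate to
#' the configured time constant.
#'
#' @param t_after_onset Time since bolus onset, s (negative values give 1).
#' @param config A [coro_config()].
#' @return Dimensionless flow multiplier, same length as `t_after_onset`.
#' @export
hyperemia_envelope <- function(t_after_onset, config) {
  tp <- config$hyperemia_time_to_peak
  alpha <- tp / config$hyperemia_decay_tau
  g <- numeric(length(t_after_onset))
  pos <- t_after_onset > 0
  x <- t_after_onset[pos] / tp
  g[pos] <- exp(alpha * (log(x) + 1 - x))
  1 + (config$hyperemic_gain - 1) * g
}
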