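---
title: "Assessing coronary flow regulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing coronary flow regulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cororeg)
```

## The two assessments

`cororeg` evaluates coronary blood flow regulation from a distal coronary
pressure trace (mmHg) and a Doppler flow-velocity trace (cm/s) sampled on a
common uniform grid. Velocity stands in for volumetric flow throughout,
under the usual assumption that the insonated cross-section is constant so
velocity and flow changes are proportional. Two complementary questions are
answered:

1. **Metabolic regulation** — how much can flow increase under maximal
   pharmacological vasodilation? Quantified by the coronary flow reserve
   (CFR), the ratio of hyperemic to baseline flow, and by the hyperemic
   microvascular resistance (HMR), pressure over flow at peak vasodilation.
2. **Autoregulation** — down to which perfusion pressure is flow held
   constant? Quantified by the lower autoregulatory breakpoint of the
   pressure–flow relationship obtained while a balloon progressively lowers
   distal pressure.

All computation happens on *beat means*: the recording is segmented into
foot-to-foot cardiac cycles and each beat is reduced to its mean pressure
and mean velocity. This makes results independent of intra-beat waveform
shape, which matters because that shape is exactly what instrumentation and
species differences change most.

## Beat detection

Beats are delimited on the **pressure** channel: pressure pulsatility
persists while the balloon collapses flow, so pressure remains a reliable
timing signal when velocity does not. Systolic upstrokes are found where the
pressure slope — a central difference over a ~40 ms window — exceeds 40% of
its 99.5th percentile; the smoothing window and the quantile (rather than
the absolute maximum) make the detector indifferent to isolated step
artifacts such as segment seams in stitched recordings. Candidate upstrokes
closer than a refractory period of `0.6 * (60 / expected_rate)` s to the
previous accepted one are discarded, which suppresses dicrotic-notch double
counting. Each beat onset is the diastolic foot: the pressure minimum in the
half cycle preceding the upstroke. A constant (non-pulsatile) trace has no
feet and yields an empty beat series rather than an error.

Whether beats should be gated on ECG instead is a genuine open choice; ECG
gating is out of scope here, and the pressure-foot convention is recorded as
this package's definition of a beat.

## Hyperemia indices

For each vasodilator bolus:

- **Baseline flow**: mean velocity of the *last five* successive beats
  before bolus onset. The five-beat rule fixes the averaging depth; placing
  the window immediately before the event minimizes drift between baseline
  and measurement.
- **Hyperemic flow**: the maximal mean over any *three successive* beats
  after onset, searched within a 60 s window truncated at the next annotated
  event so replicates never overlap. Ties go to the earliest window so
  results are deterministic.
- **Hyperemic pressure**: mean beat pressure over the same three beats.
- `CFR = hyperemic / baseline`; `HMR = pressure / hyperemic flow`.
- Classification of CFR uses strict inequalities: above 3.0 normal, below
  2.0 pathological, the closed interval `[2.0, 3.0]` intermediate.

Replicates are aggregated as the arithmetic mean of per-replicate indices
(mean of ratios, not ratio of means) — the convention under which repeated
measurements of a ratio index are usually reported. The two differ whenever
baseline flow varies between replicates, so the choice is stated rather than
implied.

## The autoregulation curve and its breakpoint

Beat (pressure, velocity) coordinates from the ramp window are pooled and
averaged in pressure bins of 5 mmHg. Bin edges are anchored at multiples of
the width (…, 40, 45, 50, …), half-open on the upper side; each retained bin
contributes its *member-mean* pressure (not the bin center) and member-mean
flow, weighted equally in the regressions regardless of member count.
Count-weighted regression is available as an option but is off by default,
matching the pool-and-average construction of the curve.

The binned curve is split into every contiguous low/high partition with at
least `min_segment = 3` bins per side (a 2-point line fits exactly and would
dominate any goodness-of-fit ranking), and each side is fitted by ordinary
least squares. The **best-fitted pair** is the split with the smallest
pooled residual sum of squares; both limbs' R² values are reported and their
sum is kept as the fit's `score`. The breakpoint is the intersection of the
two selected lines, flagged `in_range = FALSE` (with a warning, never a
rejection) when it falls outside the observed bin-pressure range.

Selection by residual error rather than by maximizing summed R² is a
deliberate design decision. R² is a *relative* measure: on a correct,
near-flat plateau the ordinate variance is mostly noise, so the plateau's R²
tends to zero even when its line is right, and a summed-R² ranking then
prefers splits that fold the knee into one limb, biasing the breakpoint by
several mmHg under realistic beat noise. Minimizing the pooled residual sum
of squares is the standard two-segment least-squares criterion, ranks
exactly the pairs of lines that track the data best, and coincides with the
R² ranking whenever both limbs have genuine slope. Ties (e.g. exactly
collinear data) fall back to the higher summed R², then the lower split
index. Two further conventions make degenerate inputs well-defined: a
segment with zero ordinate variance and zero residual gets R² = 1 (a perfect
plateau is a perfect fit), and parallel best lines raise an error that names
the selected split instead of returning a meaningless intersection.

## The synthetic generator

The generator exists so that each estimator can be validated against a known
truth. It emulates the statistical structure of a healthy closed-chest
porcine preparation; defaults (all overridable through `coro_config()`):

| parameter | default | meaning |
|---|---|---|
| `heart_rate` | 85 bpm | carrier frequency of the pulsatile templates |
| `mean_pressure` | 89 mmHg | resting mean distal pressure |
| `pulse_pressure` | 40 mmHg | peak-to-trough pulsatile amplitude |
| `baseline_velocity` | 19.1 cm/s | resting flow velocity |
| `hyperemic_gain` | 3.0 | peak bolus flow as a multiple of baseline |
| `hyperemia_time_to_peak` / `hyperemia_decay_tau` | 8 s / 15 s | gamma-variate transient shape |
| `hyperemic_pressure_drop` | 28 mmHg | distal pressure dip at peak hyperemia (to ~61 mmHg) |
| `breakpoint_pressure` | 49 mmHg | knot of the two-limb steady-state curve |
| `zero_flow_pressure` | 10 mmHg | pressure intercept of the ischemic limb |
| `plateau_slope` | 0.02 (cm/s)/mmHg | slight positive plateau slope |
| `ramp_start/end_pressure`, `ramp_duration` | 85→20 mmHg, 180 s | balloon ramp |
| `beat_noise_sd_velocity` / `_pressure` | 1.5 cm/s / 2 mmHg | per-beat Gaussian noise |
| `sampling_rate` | 250 Hz | sample grid |

Design notes, in decreasing order of consequence:

- **Steady-state curve.** Above the breakpoint, flow follows a line of slope
  `plateau_slope` anchored to `baseline_velocity` at `ramp_start_pressure`;
  below, a line through `(zero_flow_pressure, 0)` and the plateau value at
  the knot, making the model continuous there. The zero-flow pressure is a
  modeling addition — the ischemic limb needs an intercept and 10 mmHg is a
  physiologically plausible value; only its plausibility matters, since
  recovery is judged against the configured knot, not the intercept.
- **Noise model.** Independent Gaussian perturbations per *beat* on
  beat-mean velocity and pressure, because the downstream estimators consume
  beat means — beat-level noise is the scale that matters. Sample-level
  sensor noise is deliberately absent. The per-beat offsets are applied as
  steps with a 0.1 s cosine cross-fade at beat boundaries so the composite
  trace stays continuous; the cross-fade shaves a few percent off the
  effective per-beat SD, a fair trade for not injecting artificial upstrokes
  into the very signal the beat detector reads.
- **Intra-beat shape.** Pressure: half-sinusoid systole (35% of the cycle,
  stretched so end-systole sits on the downslope) plus an exponential
  diastolic decay pulled linearly to zero at end-diastole; zero mean over
  the cycle exactly (closed-form normalization), peak-to-trough equal to
  `pulse_pressure`. Velocity: a strictly positive diastolic-dominant
  multiplier with exact unit mean, its swing proportional to
  `pulse_pressure` so a non-pulsatile configuration degenerates cleanly to
  the analytic envelope. Because analyses use beat means, these shapes
  affect realism, not results.
- **Hyperemia transient.** A gamma-variate with shape exponent
  `time_to_peak / decay_tau`: smooth, unimodal, exactly peak-calibrated to
  the gain, with the configured asymptotic decay constant.
- **Ramp.** Continuous linear decline by default; a `"step"` mode (5-mmHg
  steps, 20 s dwell) reproduces manual stepwise balloon inflation for
  fidelity checks. Beat velocity during the ramp is the steady-state curve
  evaluated at that beat's *noisy* mean pressure, plus velocity noise — the
  pressure the analyst sees is the pressure the flow responded to.
- **Protocol.** `generate_experiment()` chains rest (60 s), three adenosine
  and three bradykinin bolus segments (75 s each, onset at 20 s, the
  pre-onset window doubling as return-to-baseline), a 15 s gap, and the
  ramp, with the cardiac phase running continuously across segments. The
  annotation schedule is fixed by the durations; only noise depends on the
  seed, and per-segment seeds are derived from the configuration seed so
  identical configurations reproduce recordings bitwise.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real recordings: systemic circulation and its
feedback (cardiac output, pulmonary pressures), autonomic tone, drug
pharmacokinetics beyond the flow envelope, vasospasm, arrhythmia and ectopy,
Doppler spectral noise and wire artifacts, respiratory modulation, and
hysteresis between balloon inflation and deflation. Results on real data
additionally depend on signal quality and on the velocity-as-flow
assumption holding.

## Validation problem sizes

The test suite validates each rule against an independent oracle (closed-form
normal equations for OLS, exhaustive enumeration for the split search and the
3-beat window search) and checks parameter recovery end to end. The
Monte-Carlo studies use 100 simulated ramps with true breakpoints drawn
uniformly from 42–55 mmHg — the physiological range of the lower limit of
autoregulation — under default noise, requiring a median absolute error
within 2.5 mmHg with at least 95% of intersections in range, and 34 bolus
simulations per hyperemic gain in {2.0, 2.5, 3.0}, requiring the mean
estimated CFR within 0.1 of the gain. These sizes give stable medians and
means while keeping the full suite fast; `scripts/acceptance.R` re-runs both
studies from scratch at the same sizes.

A note on the CFR recovery: the hyperemic-flow rule takes a *maximum* over
3-beat windows, so under noise it carries a small positive selection bias
(visible in `analysis/04_parameter_recovery.R`). That bias is a property of
the published selection rule itself, not of this implementation, and stays
well inside the 0.1 tolerance at the default noise level.

## Known limitations

- The breakpoint search is restricted to contiguous splits of the binned
  curve; a sigmoid (logistic) model of the whole relationship, the upper
  autoregulatory limit, and zero-flow-pressure extrapolation are out of
  scope.
- Beat detection assumes a roughly known heart rate (30–250 bpm) and a
  pulsatile pressure of at least ~0.5 mmHg amplitude; it performs no
  arrhythmia handling beyond the refractory rule.
- With fewer than 3 bins on either side of the true knot (short ramps, or
  windows that never cross the breakpoint) the two-segment fit is
  impossible and the analysis reports an error rather than extrapolating.
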