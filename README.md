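# cororeg

Assessment of coronary blood flow regulation from intracoronary pressure and
Doppler flow-velocity recordings.

Coronary blood flow is governed by two mechanisms that are usually studied
separately: **metabolic regulation**, quantified by the coronary flow reserve
(CFR) after pharmacological vasodilation, and **autoregulation**, the
maintenance of near-constant flow across perfusion pressures down to a lower
breakpoint below which flow becomes pressure-dependent (the ischemic
relation). `cororeg` implements both assessments as one reproducible
pipeline for physiologists and interventional researchers working with
pressure/Doppler wire recordings, together with a seeded synthetic
hemodynamics generator so that every stage can be exercised and validated
without animal data.

## Method

Recordings are segmented into foot-to-foot cardiac cycles on the pressure
waveform, and each beat is reduced to its mean pressure P̄ and mean flow
velocity v̄ (velocity is the flow surrogate: flow and velocity changes are
proportional in a vessel of fixed cross-section).

**Hyperemia indices**, per vasodilator bolus (adenosine or bradykinin):

- baseline flow `Q_b` = mean v̄ over the last 5 successive resting beats;
- hyperemic flow `Q_h` = maximal mean v̄ over any 3 successive post-bolus
  beats;
- hyperemic pressure `P_h` = mean P̄ over that same 3-beat window;
- `CFR = Q_h / Q_b` (normal > 3.0, pathological < 2.0);
- `HMR = P_h / Q_h` in mmHg/(cm/s), the hyperemic microvascular resistance.

**Autoregulatory breakpoint**, from a balloon-driven pressure decline: the
beat (P̄, v̄) coordinates are pooled and averaged in 5-mmHg pressure bins;
every contiguous split of the binned curve into a low-pressure (ischemic) and
a high-pressure (plateau) segment, each of ≥ 3 bins, is fitted by paired
ordinary least-squares lines, and the best-fitted pair — the split minimizing
the pooled residual sum of squares, with each limb's R² reported — defines
the breakpoint as the intersection of its two lines.

The synthetic generator produces pulsatile pressure (85 bpm, mean 89 mmHg),
baseline velocity 19.1 cm/s, gamma-variate bolus hyperemia that triples flow
while distal pressure dips to ~61 mmHg, and a linear balloon ramp crossing a
configurable breakpoint (default 49 mmHg), with independent per-beat Gaussian
noise on beat-mean pressure and velocity.

## Worked example

```r
library(cororeg)
rec <- generate_experiment(coro_config(seed = 5))  # full synthetic protocol
report <- run_pipeline(rec, seed = 5)
print(report)
#> <analysis_report>
#>   998 beat(s) analyzed; 6 hyperemia result(s)
#>        drug n_replicates baseline_flow hyperemic_flow hyperemic_pressure  cfr
#>   adenosine            3          18.8           57.7               61.2 3.07
#>  bradykinin            3          19.2           57.6               61.3 3.00
#>   hmr
#>  1.06
#>  1.06
#> <breakpoint_fit> breakpoint 49.8 mmHg at 18.1 cm/s (in range)
#>   ischemic: slope 0.446, R2 0.981 (7 bins)
#>   plateau:  slope 0.043, R2 0.926 (8 bins)
```

Reading: across three replicates per drug, resting flow ~19 cm/s roughly
triples under either vasodilator (CFR ≈ 3, a healthy reserve at the clinical
threshold), distal pressure at peak hyperemia is ~61 mmHg, giving an HMR of
~1.06 mmHg/(cm/s); the balloon ramp locates the lower limit of autoregulation
at ~50 mmHg — flow is held near 18 cm/s above it (flat plateau limb) and
falls at 0.45 (cm/s)/mmHg below it (ischemic limb). The configured truths
were CFR gain 3.0 and breakpoint 49 mmHg.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_experiment.R   # protocol -> recording.csv + sidecars
Rscript analysis/02_hyperemia_indices.R     # CFR/HMR per replicate and drug
Rscript analysis/03_autoregulation_breakpoint.R  # binned curve + breakpoint
Rscript analysis/04_parameter_recovery.R    # Monte-Carlo estimator validation
```

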