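#!/usr/bin/env Rscript
# Autoregulation curve and lower breakpoint from the balloon-ramp window:
# beat pressure-flow coordinates averaged in 5-mmHg bins, two-segment
# regression, breakpoint at the intersection of the two fitted lines.
# Requires results/recording.csv from analysis/01_simulate_experiment.R.

suppressPackageStartupMessages(library(cororeg))

if (!file.exists("results/recording.csv")) {
  stop("run analysis/01_simulate_experiment.R first")
}
rec <- read_recording("results/recording.csv", "results/annotations.json")
beats <- detect_beats(rec)
ann <- annotations(beats)
fit <- analyze_ramp(beats,
                    ann$onset_s[ann$kind == "ramp_start"][1],
                    ann$onset_s[ann$kind == "ramp_end"][1])

write.csv(fit$bins, "results/autoregulation_bins.csv", row.names = FALSE)
jsonlite::write_json(list(
  breakpoint_pressure = fit$breakpoint_pressure,
  breakpoint_flow = fit$breakpoint_flow,
  ischemic = fit$ischemic[c("slope", "intercept", "r_squared", "n_points")],
  plateau = fit$plateau[c("slope", "intercept", "r_squared", "n_points")],
  score = fit$score, in_range = fit$in_range
), "results/breakpoint.json", auto_unbox = TRUE, digits = NA)

message("Binned autoregulation curve (results/autoregulation_bins.csv):")
print(fit$bins, row.names = FALSE, digits = 4)
message("\nTwo-segment fit:")
print(fit)
message(sprintf(
  "\nBelow ~%.0f mmHg flow becomes pressure-dependent (ischemic slope %.2f (cm/s)/mmHg);\nabove it the plateau holds flow near %.1f cm/s.",
  fit$breakpoint_pressure, fit$ischemic$slope, fit$breakpoint_flow))
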