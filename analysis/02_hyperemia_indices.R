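#!/usr/bin/env Rscript
# Coronary pressure-flow derived indices from the simulated protocol:
# baseline flow (last 5 resting beats), hyperemic flow (best 3-beat window),
# hyperemic pressure, CFR and HMR, per bolus replicate and per drug.
# Requires results/recording.csv from analysis/01_simulate_experiment.R.

suppressPackageStartupMessages(library(cororeg))

if (!file.exists("results/recording.csv")) {
  stop("run analysis/01_simulate_experiment.R first")
}
rec <- read_recording("results/recording.csv", "results/annotations.json")
report <- run_pipeline(rec)

write.csv(report$hyperemia, "results/hyperemia_indices.csv", row.names = FALSE)
write.csv(report$hyperemia_means, "results/hyperemia_means.csv",
          row.names = FALSE)

message("Per-replicate indices (results/hyperemia_indices.csv):")
print(report$hyperemia, row.names = FALSE, digits = 4)
message("\nPer-drug means of the per-replicate indices:")
print(report$hyperemia_means, row.names = FALSE, digits = 4)
message(sprintf(
  "\nBoth vasodilators roughly triple flow: CFR %.2f (adenosine) and %.2f (bradykinin),\nwith hyperemic pressure ~%.0f mmHg and HMR ~%.2f mmHg/(cm/s).",
  report$hyperemia_means$cfr[report$hyperemia_means$drug == "adenosine"],
  report$hyperemia_means$cfr[report$hyperemia_means$drug == "bradykinin"],
  mean(report$hyperemia$hyperemic_pressure), mean(report$hyperemia$hmr)))
if (length(report$warnings)) {
  message("Warnings: ", paste(report$warnings, collapse = "; "))
}
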