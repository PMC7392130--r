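#!/usr/bin/env Rscript
# Generate the synthetic coronary protocol used by the downstream analyses:
# rest, 3 adenosine + 3 bradykinin boluses, then a balloon pressure ramp.
# Writes results/recording.csv + results/annotations.json + results/config.json.

suppressPackageStartupMessages(library(cororeg))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 42L
dir.create("results", showWarnings = FALSE)

cfg <- coro_config(seed = seed)
message("Simulating the full protocol with the default healthy-pig configuration:")
print(cfg)

rec <- generate_experiment(cfg)
write_recording(rec, "results/recording.csv", "results/annotations.json")
write_config(cfg, "results/config.json")

message(sprintf(
  "Wrote %.0f s of pressure/velocity at %g Hz (%d samples) with %d annotations.",
  length(rec$time) / rec$sampling_rate, rec$sampling_rate,
  length(rec$time), nrow(rec$annotations)))
print(rec$annotations, row.names = FALSE)
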