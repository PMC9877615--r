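#!/usr/bin/env Rscript

# Stage 1 — simulate the study.
#
# Generates the default synthetic world: 105 natural-image-like stimuli with
# a latent figure-ground ambiguity each, 10 observers x 8 variant trials of
# forced-choice psychophysics, and 100 V4-like neurons (half of them truly
# figure-ground modulated) emitting Poisson spike trains over the 210
# original/mirror patches at 10 repeats. Writes the measured tables —
# trials, spikes, grating maps, patch masks, placements — plus the ground
# truth that later stages never read.

suppressPackageStartupMessages(library(fgcons))
suppressPackageStartupMessages(library(readr))

seed <- if (length(commandArgs(TRUE)) > 0) {
  as.integer(commandArgs(TRUE)[1])
} else 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- world_config(seed = seed)
sim <- suppressWarnings(simulate_study(cfg))

write_csv(sim$trials, file.path(out, "trials.csv"))
write_spike_table(sim$spikes, file.path(out, "spikes.csv"),
                  trial_grid = trial_grid(sim$world$patches,
                                          sim$world$neurons$neuron_id,
                                          cfg$n_repeats))
write_csv(sim$gratings, file.path(out, "gratings.csv"))
write_csv(sim$world$patches, file.path(out, "patches.csv"))
write_csv(sim$world$placements, file.path(out, "placements.csv"))
write_csv(sim$ground_truth$labels, file.path(out, "true_labels.csv"))
jsonlite::write_json(
  list(stimuli = sim$world$stimuli, neurons = sim$world$neurons),
  file.path(out, "ground_truth.json"), dataframe = "rows", digits = NA)
yaml::write_yaml(unclass(cfg), file.path(out, "world_config.yaml"))

cat(sprintf(
  "simulated %d stimuli (%d patches), %d observers, %d neurons (%d built modulated), %d spikes; seed %d\n",
  nrow(sim$world$stimuli), nrow(sim$world$patches), cfg$n_participants,
  nrow(sim$world$neurons), sum(sim$world$neurons$is_fg),
  nrow(sim$spikes), seed))
cat("tables written under", out, "\n")
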