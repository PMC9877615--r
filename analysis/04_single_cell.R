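#!/usr/bin/env Rscript

# Stage 4 — single-cell neural consistency.
#
# For every screened figure-ground neuron, pools the 400 stimulus-window
# trials of each 20-stimulus group (EASY and HARD), fits the
# accuracy-maximising spike-count threshold per group, and compares the
# resulting neural consistencies with a one-sided paired (sign-flip)
# permutation test.

suppressPackageStartupMessages(library(fgcons))
suppressPackageStartupMessages(library(dplyr))

seed <- if (length(commandArgs(TRUE)) > 0) {
  as.integer(commandArgs(TRUE)[1])
} else 1L

spikes <- read_spike_table("results/data/spikes.csv")
patches <- readr::read_csv("results/data/patches.csv",
                           show_col_types = FALSE)
labels <- readr::read_csv("results/labels.csv", show_col_types = FALSE)
pc_tab <- readr::read_csv("results/pc_table.csv", show_col_types = FALSE)
scr <- readr::read_csv("results/screening.csv", show_col_types = FALSE)

fg_ids <- scr$neuron_id[scr$fg_modulated]
n_rep <- max(spikes$rep)
grid <- trial_grid(patches, fg_ids, n_rep)
stim <- spike_counts(spikes[spikes$neuron_id %in% fg_ids, ], grid, 50, 250)

groups <- patches |>
  inner_join(pc_tab[, c("stimulus_id", "group20")], by = "stimulus_id") |>
  filter(.data$group20 != "neither") |>
  transmute(patch_id = .data$patch_id, group = as.character(.data$group20))
nc_tab <- compute_nc_table(stim, labels, groups)
readr::write_csv(nc_tab, "results/nc_table.csv")

cmp <- compare_nc_groups(nc_tab, n_perm = 10000,
                         seed = derive_seed(seed, "nc_perm"))
cat(sprintf("neural consistency over %d neurons: EASY %.1f%% (SD %.1f), HARD %.1f%% (SD %.1f)\n",
            cmp$n, cmp$mean_easy, cmp$sd_easy, cmp$mean_hard, cmp$sd_hard))
cat(sprintf("one-sided paired permutation p = %.2g; %.1f%% of neurons higher with EASY\n",
            cmp$p, 100 * cmp$fraction_greater))
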