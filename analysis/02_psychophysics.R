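#!/usr/bin/env Rscript

# Stage 2 — perceptual consistency and reaction times.
#
# From the forced-choice trial table: per-stimulus perceptual consistency
# (PC), mean reaction time, the EASY/HARD stimulus groups (top and bottom
# 20, and 50 for the population analysis), the shape of the PC distribution
# and the PC-RT relation.

suppressPackageStartupMessages(library(fgcons))
suppressPackageStartupMessages(library(dplyr))

trials <- read_psych_trials("results/data/trials.csv")
pc <- suppressWarnings(compute_pc(trials))
rt <- compute_rt(trials)
pc_tab <- left_join(pc, rt, by = "stimulus_id")
g20 <- suppressWarnings(rank_groups(pc_tab, 20))
g50 <- suppressWarnings(rank_groups(pc_tab, 50))
pc_tab$group20 <- g20$group
pc_tab$group50 <- g50$group
readr::write_csv(pc_tab, "results/pc_table.csv")

s <- pc_summary(pc_tab)
cat(sprintf("PC across %d stimuli: mean %.1f%%, SD %.1f%% (Gaussian KS p = %.3f)\n",
            nrow(pc_tab), s$mean, s$sd, s$normality_p))
rel <- pc_rt_relation(pc_tab)
cat(sprintf("PC vs z-scored RT: Pearson r = %.2f, slope = %.4f per PC point (p = %.2g)\n",
            rel$pearson_r, rel$slope, rel$slope_p))
cat(sprintf("EASY group PC range: %.1f-%.1f; HARD group: %.1f-%.1f\n",
            min(pc_tab$pc[pc_tab$group20 == "EASY"]),
            max(pc_tab$pc[pc_tab$group20 == "EASY"]),
            min(pc_tab$pc[pc_tab$group20 == "HARD"]),
            max(pc_tab$pc[pc_tab$group20 == "HARD"])))
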