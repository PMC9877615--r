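make_pair_counts <- function(pref_mean, non_mean, n_stim = 10L,
                             n_rep = 10L, same_label_stim = character(0)) {
  rows <- lapply(seq_len(n_stim), function(i) {
    sid <- sprintf("s%02d", i)
    labs <- if (sid %in% same_label_stim) c("F", "F") else c("F", "G")
    tidyr::crossing(patch_id = paste0(sid, c("_orig", "_mirr")),
                    rep = seq_len(n_rep)) |>
      dplyr::mutate(stimulus_id = sid,
                    label = rep(labs, each = n_rep),
                    count = rep(c(pref_mean, non_mean), each = n_rep))
  })
  dplyr::bind_rows(rows)
}

test_that("delta-R is the preferred-minus-nonpreferred mean count, flips
           sign with preference, and applies the pair exclusion rules", {
  d <- make_pair_counts(10, 4, same_label_stim = "s03")
  res <- delta_r(d, "F")
  ok <- res[!res$excluded, ]
  expect_equal(unique(ok$delta_r), 6)
  expect_equal(res$reason[res$stimulus_id == "s03"],
               "pair shares one FG label")

  flipped <- delta_r(d, "G")
  expect_equal(unique(flipped$delta_r[!flipped$excluded]), -6)

  silent <- make_pair_counts(0, 0, n_stim = 2)
  rs <- delta_r(silent, "F")
  expect_true(all(rs$excluded))
  expect_true(all(rs$reason == "pair did not evoke responses"))
  # equal non-zero means give exactly zero
  eq <- delta_r(make_pair_counts(5, 5, n_stim = 2), "F")
  expect_equal(unique(eq$delta_r), 0)
})

test_that("PC-to-delta-R correlation is 1 for a monotone relation, skips
           undersampled or degenerate neurons, and is centred under the
           null", {
  pc_tab <- tibble::tibble(stimulus_id = sprintf("s%02d", 1:20),
                           pc = seq(55, 95, length.out = 20))
  mono <- tibble::tibble(stimulus_id = pc_tab$stimulus_id,
                         delta_r = seq(0.5, 8, length.out = 20),
                         excluded = FALSE, reason = NA)
  res <- suppressWarnings(pc_delta_r_correlation(pc_tab, list(n1 = mono)))
  expect_equal(res$per_neuron$spearman_rho, 1)
  expect_gt(res$per_neuron$ols_slope, 0)

  small <- mono[1:3, ]
  skipped <- pc_delta_r_correlation(pc_tab, list(n2 = small))
  expect_true(skipped$per_neuron$skipped)
  flat <- dplyr::mutate(mono, delta_r = 2)
  expect_match(pc_delta_r_correlation(pc_tab,
                                      list(n3 = flat))$per_neuron$reason,
               "zero-variance")

  set.seed(12)
  null_tables <- lapply(1:30, function(i) {
    dplyr::mutate(mono, delta_r = rnorm(20))
  })
  names(null_tables) <- sprintf("n%02d", 1:30)
  null_res <- pc_delta_r_correlation(pc_tab, null_tables)
  expect_lt(abs(null_res$summary$mean_rho),
            2 * null_res$summary$sd_rho / sqrt(30) + 0.1)
})

test_that("group PSTHs estimate a homogeneous Poisson rate flatly and
           normalisation fixes the per-neuron peak at one", {
  set.seed(44)
  # one neuron, 2 patches x many repeats at 20 Hz over [-100, 300)
  n_rep <- 400L
  trains <- tidyr::crossing(patch_id = c("pA", "pB"), rep = seq_len(n_rep))
  spikes <- dplyr::bind_rows(lapply(seq_len(nrow(trains)), function(i) {
    hits <- which(runif(400) < 0.02)
    if (length(hits) == 0) return(NULL)
    tibble::tibble(neuron_id = "n1", patch_id = trains$patch_id[i],
                   rep = trains$rep[i], t_ms = hits - 101L)
  }))
  labels <- tibble::tibble(neuron_id = "n1", patch_id = c("pA", "pB"),
                           label = c("F", "G"))
  prefs <- tibble::tibble(neuron_id = "n1", preference = "F")
  ps <- build_group_psth(spikes, c("pA", "pB"), labels, prefs, n_rep)
  expect_equal(mean(ps$pref), 20, tolerance = 0.05)
  expect_equal(mean(ps$nonpref), 20, tolerance = 0.05)
  expect_lt(sd(moving_average(ps$pref, 50, 1)[50:350]), 1)

  # normalisation: baseline-subtracted peak equals one by construction
  spikes2 <- dplyr::mutate(spikes,
                           t_ms = ifelse(.data$patch_id == "pA" &
                                           .data$t_ms >= 100,
                                         .data$t_ms, .data$t_ms))
  psn <- build_group_psth(spikes, c("pA", "pB"), labels, prefs, n_rep,
                          normalize = TRUE)
  expect_equal(max(psn$pref, psn$nonpref), 1, tolerance = 1e-12)
})

test_that("modulation latency recovers a ramp onset, is invariant to
           uniform rescaling, and flags zero modulation as invalid", {
  t <- -100:299
  pref <- 20 + pmax(0, pmin(t - 70, 80)) * 0.1
  nonpref <- rep(20, length(t))
  ps <- list(t = t, pref = pref, nonpref = nonpref)
  lat <- modulation_latency(ps, group = "EASY")
  expect_true(lat$valid)
  expect_gt(lat$latency_ms, 60)
  expect_lt(lat$latency_ms, 85)

  scaled <- list(t = t, pref = 3 * pref, nonpref = 3 * nonpref)
  expect_equal(modulation_latency(scaled)$latency_ms, lat$latency_ms,
               tolerance = 1e-9)

  flat <- list(t = t, pref = nonpref, nonpref = nonpref)
  lf <- modulation_latency(flat)
  expect_false(lf$valid)
  expect_true(is.na(lf$latency_ms))
})

test_that("with ambiguity-dependent onsets switched off, EASY and HARD
           latencies agree within the fit tolerance", {
  cfg <- small_world_config(seed = 2, onset_slope_ms = 0, n_neurons = 30L,
                            p_fg = 1)
  sim <- suppressWarnings(simulate_study(cfg))
  pc <- suppressWarnings(compute_pc(sim$trials))
  g <- suppressWarnings(rank_groups(pc, 6))
  labs <- sim$ground_truth$labels
  prefs <- sim$world$neurons[, c("neuron_id", "preference")]
  lat <- sapply(c("EASY", "HARD"), function(grp) {
    gp <- sim$world$patches$patch_id[
      sim$world$patches$stimulus_id %in% g$stimulus_id[g$group == grp]]
    modulation_latency(build_group_psth(sim$spikes, gp, labs, prefs,
                                        cfg$n_repeats))$latency_ms
  })
  expect_lt(abs(lat[1] - lat[2]), 25)
})
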