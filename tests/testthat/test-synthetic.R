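test_that("world generation is deterministic, respects config bookkeeping,
           and validates inputs with itemised errors", {
  cfg <- world_config(seed = 5)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$stimuli, w2$stimuli)
  expect_identical(w1$neurons, w2$neurons)
  expect_equal(nrow(w1$stimuli), 105)
  expect_equal(nrow(w1$patches), 210)
  expect_equal(sum(w1$neurons$is_fg), 50)

  none <- generate_world(world_config(n_stimuli = 10, n_neurons = 8,
                                      p_fg = 0, seed = 1))
  expect_false(any(none$neurons$is_fg))

  err <- tryCatch(world_config(p_fg = 2, gain = -1), error = identity)
  expect_match(conditionMessage(err), "p_fg")
  expect_match(conditionMessage(err), "gain")
})

test_that("mirror patches carry swapped region-under-center labels", {
  w <- generate_world(world_config(n_stimuli = 30, n_neurons = 10,
                                   nonfg_frac = 0, seed = 3))
  lab <- true_labels(w) |>
    dplyr::mutate(stimulus_id = sub("_(orig|mirr)$", "", .data$patch_id),
                  kind = sub("^.*_", "", .data$patch_id)) |>
    tidyr::pivot_wider(id_cols = c("neuron_id", "stimulus_id"),
                       names_from = "kind", values_from = "label")
  expect_true(all(lab$orig != lab$mirr))
  expect_true(all(sort(unique(c(lab$orig, lab$mirr))) == c("F", "G")))
})

test_that("a deterministic observer gives PC = 100 and a Bernoulli(0.5)
           observer matches the exact max-statistic bias", {
  cfg <- world_config(n_stimuli = 50, n_neurons = 2, seed = 8)
  w <- generate_world(cfg)
  w$stimuli$theta <- 1
  pc <- compute_pc(generate_psych_trials(w))
  expect_true(all(pc$pc == 100))

  # closed form for theta = 0: E[max(a, 8-a)]/8 over Binomial(8, 1/2)
  a <- 0:8
  exact <- sum(choose(8, a) * 0.5^8 * pmax(a, 8 - a) / 8) * 100
  expect_equal(exact, 63.671875, tolerance = 1e-9)
  w$stimuli$theta <- 0
  pc0 <- suppressWarnings(compute_pc(generate_psych_trials(w)))
  expect_lt(abs(mean(pc0$pc) - exact), 2.5) # 50 stimuli x 10 participants
})

test_that("estimated PC is a consistent estimator of its closed-form
           conditional expectation", {
  cfg <- world_config(n_stimuli = 800, n_neurons = 2, seed = 13)
  w <- generate_world(cfg)
  pc <- suppressWarnings(compute_pc(generate_psych_trials(w)))
  d <- dplyr::left_join(pc, w$stimuli[, c("stimulus_id", "theta")],
                        by = "stimulus_id")
  # E[PC | theta] under the Bernoulli observer: E[max(a, 8-a)]/8 over
  # Binomial(8, 0.5 + 0.5 theta); the naive 50 + 50 theta line ignores the
  # max-statistic bias at low theta
  a <- 0:8
  exp_pc <- vapply(d$theta, function(th) {
    p <- 0.5 + 0.5 * th
    100 * sum(dbinom(a, 8, p) * pmax(a, 8 - a) / 8)
  }, numeric(1))
  fit <- lm(d$pc ~ exp_pc)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_lt(abs(mean(d$pc - exp_pc)), 0.3)
})

test_that("reaction times honour the deadline and decrease with theta", {
  w <- generate_world(world_config(n_stimuli = 60, n_neurons = 2,
                                   seed = 21))
  tr <- generate_psych_trials(w)
  expect_true(all(tr$rt_ms > 0 & tr$rt_ms <= 1000))
  rt <- compute_rt(tr) |>
    dplyr::left_join(w$stimuli[, c("stimulus_id", "theta")],
                     by = "stimulus_id")
  expect_lt(cor(rt$theta, rt$rt_mean_ms), -0.8)
})

test_that("spike generation is seed-deterministic and matches the
           programmed rate integrals", {
  cfg <- world_config(n_stimuli = 6, n_neurons = 2, n_repeats = 400,
                      p_fg = 0, nonfg_frac = 0, seed = 31)
  w <- generate_world(cfg)
  sp1 <- generate_spike_trains(w)
  sp2 <- generate_spike_trains(w)
  expect_identical(sp1, sp2)

  grid <- trial_grid(w$patches, w$neurons$neuron_id, cfg$n_repeats)
  stim <- spike_counts(sp1, grid, 50, 250)
  # [50, 250) at 20 Hz evoked (visual latency 50 ms): 4 expected spikes
  expect_equal(mean(stim$count), 4, tolerance = 0.02)
  pre <- spike_counts(sp1, grid, -50, 50)
  # [-50, 50) spans 100 ms of 10 Hz spontaneous rate: 1 expected spike
  expect_equal(mean(pre$count), 1, tolerance = 0.04)
})

test_that("modulated neurons raise preferred-label counts by the programmed
           transient integral and unmodulated neurons never step", {
  cfg <- world_config(n_stimuli = 40, n_neurons = 4, n_repeats = 100,
                      p_fg = 0.5, p_f_pref = 1, nonfg_frac = 0,
                      mod_dispersion = 0, seed = 17)
  w <- generate_world(cfg)
  sp <- generate_spike_trains(w)
  labs <- true_labels(w)
  grid <- trial_grid(w$patches, w$neurons$neuron_id, cfg$n_repeats)
  stim <- spike_counts(sp, grid, 50, 250) |>
    dplyr::left_join(labs, by = c("neuron_id", "patch_id")) |>
    dplyr::left_join(w$neurons[, c("neuron_id", "is_fg")],
                     by = "neuron_id") |>
    dplyr::left_join(w$patches[, c("patch_id", "stimulus_id")],
                     by = "patch_id") |>
    dplyr::left_join(w$stimuli[, c("stimulus_id", "theta", "onset_ms")],
                     by = "stimulus_id")
  null_fg_gap <- with(dplyr::filter(stim, !.data$is_fg),
                      mean(count[label == "F"]) - mean(count[label == "G"]))
  expect_lt(abs(null_fg_gap), 0.08)

  mod <- dplyr::filter(stim, .data$is_fg)
  gap <- mean(mod$count[mod$label == "F"]) - mean(mod$count[mod$label == "G"])
  # programmed extra spikes: evoked * gain * theta * transient integral
  integral <- with(dplyr::distinct(mod, .data$stimulus_id, .data$theta,
                                   .data$onset_ms), {
    ramp <- cfg$mod_ramp_ms / 2
    full <- pmax(0, cfg$mod_offset_ms - (onset_ms + cfg$mod_ramp_ms))
    tail <- cfg$mod_sustained * (250 - cfg$mod_offset_ms)
    mean(cfg$evoked_hz * cfg$gain * theta * (ramp + full + tail) / 1000)
  })
  expect_equal(gap, integral, tolerance = 0.12)
})
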