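# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# Forced-choice trial table where participant j answers region A `n_a[j]`
# times out of `n_variants` for a single stimulus.
make_trials_one_stimulus <- function(n_a, n_variants = 8L,
                                     stimulus_id = "s001") {
  dplyr::bind_rows(lapply(seq_along(n_a), function(j) {
    ch <- c(rep("A", n_a[j]), rep("B", n_variants - n_a[j]))
    tibble::tibble(participant_id = sprintf("p%02d", j),
                   stimulus_id = stimulus_id,
                   mirror = rep(c(FALSE, TRUE), length.out = n_variants),
                   reversal = rep(c(FALSE, TRUE), each = 2,
                                  length.out = n_variants),
                   order = rep(c(FALSE, TRUE), each = 4,
                               length.out = n_variants),
                   choice = ch,
                   rt_ms = 500)
  }))
}

# Independent brute-force threshold oracle: every integer cut 0..max+1,
# both orientations, prediction by `count >= cut` (or its complement).
brute_force_threshold_accuracy <- function(counts, labels) {
  is_f <- labels == "F"
  best <- 0
  for (cut in 0:(max(counts) + 1L)) {
    acc_high <- (sum(is_f & counts >= cut) + sum(!is_f & counts < cut)) /
      length(counts)
    best <- max(best, acc_high, 1 - acc_high)
  }
  best
}

# Independent exhaustive two-phase oracle built on lm(): every partition
# with >= 2 points per side, least total SSE.
oracle_two_phase <- function(t, y, fit_range = c(10, 150)) {
  keep <- t >= fit_range[1] & t <= fit_range[2]
  tt <- t[keep]; yy <- y[keep]
  n <- length(tt)
  best <- list(sse = Inf)
  for (m in 2:(n - 2)) {
    f0 <- lm(yy[1:m] ~ tt[1:m])
    f1 <- lm(yy[(m + 1):n] ~ tt[(m + 1):n])
    sse <- sum(residuals(f0)^2) + sum(residuals(f1)^2)
    if (sse < best$sse - 1e-15) {
      best <- list(sse = sse, m = m,
                   a0 = unname(coef(f0)[2]), b0 = unname(coef(f0)[1]),
                   a1 = unname(coef(f1)[2]), b1 = unname(coef(f1)[1]))
    }
  }
  best
}

# Gaussian-count neuron dataset for population decoding: d-prime separation
# between the class means, unit variance, `n_per_class` patches per class.
make_gaussian_dataset <- function(neuron_id, d_prime, n_per_class = 50L,
                                  center = 10) {
  n <- 2L * n_per_class
  rows <- tibble::tibble(
    patch_id = sprintf("%s_p%03d", neuron_id, seq_len(n)),
    sum_count = rnorm(n, mean = center +
                        rep(c(d_prime / 2, -d_prime / 2),
                            each = n_per_class), sd = 1),
    label = rep(c("F", "G"), each = n_per_class))
  structure(list(neuron_id = neuron_id, rows = rows, admitted = TRUE,
                 reason = NA_character_), class = "neuron_dataset")
}

# Small default-physiology world for integration tests.
small_world_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(n_stimuli = 24L, n_neurons = 12L,
                                 seed = seed), list(...))
  do.call(world_config, args)
}
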