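#' Configuration of the synthetic figure-ground world
#'
#' One latent ambiguity \eqn{\theta_i \in [0, 1]} per stimulus drives both the
#' simulated observers and the simulated neurons: observers choose the true
#' figure region with probability \eqn{0.5 + 0.5\,\theta_i} and answer faster
#' for larger \eqn{\theta_i}; modulated neurons raise their firing for
#' preferred-label patches by a factor growing with \eqn{\theta_i}, with a
#' modulation onset that is earlier for larger \eqn{\theta_i}. Sharing one
#' latent between perception and spiking builds in exactly the coupling the
#' analysis pipeline is designed to detect, so recovery of that coupling is
#' the natural acceptance surface for every stage.
#'
#' Defaults mirror the study design: 105 stimuli (each with an original and a
#' hue-inverted mirror patch), 10 observers completing 8 variant trials per
#' stimulus under a 1000-ms response deadline, and 10 spike-train repeats per
#' patch. Rate-model defaults (units in the argument list) are chosen as
#' typical anesthetised-V4 figures: 10 Hz spontaneous and 20 Hz evoked rates,
#' a ~60 ms visual response latency, figure-ground modulation onsets spanning
#' roughly 60-120 ms depending on ambiguity, and a dispersed unit-mean
#' multiplier on each neuron's per-stimulus modulation reflecting that real
#' neurons discriminate figure from ground well on some natural patches and
#' poorly on others.
#'
#' @param n_stimuli Number of stimuli (default 105).
#' @param n_participants Observers (default 10).
#' @param n_variants Variant trials per observer per stimulus (default 8).
#' @param n_repeats Spike-train repeats per patch (default 10).
#' @param n_neurons Simulated neurons (default 100).
#' @param p_fg Fraction of neurons with true figure-ground modulation
#'   (default 0.5, sized so that a 100-neuron world admits a decoding pool
#'   of a few tens of modulated neurons, comparable to the pool a several
#'   hundred neuron recording campaign yields).
#' @param p_f_pref Fraction of modulated neurons that prefer the figure side
#'   (default 0.83).
#' @param theta_shape1,theta_shape2 Beta parameters of the ambiguity
#'   distribution (default 4.5, 5.5: mean 0.45, SD 0.15 — a perceptual
#'   consistency scale centred near 72% with SD near 8 points).
#' @param rt_base_ms,rt_slope_ms Median reaction time is
#'   `rt_base_ms + rt_slope_ms * (1 - theta)` (defaults 450, 200 ms).
#' @param rt_sigma Lognormal sigma of reaction-time noise (default 0.2);
#'   draws beyond the 1000-ms deadline are redrawn.
#' @param spont_hz,evoked_hz Spontaneous and stimulus-evoked firing rates
#'   (defaults 10, 20 Hz).
#' @param gain Figure-ground modulation gain: preferred-label patches rise
#'   toward `evoked_hz * (1 + gain * theta * m)` after modulation onset
#'   (default 0.45 at the transient peak).
#' @param mod_ramp_ms Rise time of the modulation: the modulated rate grows
#'   linearly from the onset and reaches its peak `mod_ramp_ms` later
#'   (default 50 ms; 0 gives an instantaneous step).
#' @param mod_offset_ms Time (absolute, onset-relative to the stimulus, not
#'   to the modulation onset) at which the modulation transient relaxes to
#'   its sustained fraction (default 175 ms). Figure-ground modulation, like
#'   much extrastriate response modulation, is strongest in an early
#'   transient and weaker in the sustained period.
#' @param mod_sustained Sustained fraction of the peak modulation after
#'   `mod_offset_ms` (default 0.15).
#' @param mod_dispersion Variance of the unit-mean Gamma multiplier `m`
#'   applied per trial to the modulation term (default 2). Modulated neurons
#'   express their figure-ground modulation with strong trial-to-trial gain
#'   variability — some presentations modulate strongly, others barely —
#'   while unmodulated neurons remain plain Poisson. Set to 0 for
#'   deterministic modulation.
#' @param vis_latency_ms Visual response latency, identical for all
#'   conditions (default 60 ms).
#' @param onset_base_ms,onset_slope_ms Modulation onset is
#'   `onset_base_ms + onset_slope_ms * (1 - theta)` (defaults 60, 60 ms).
#' @param nonfg_frac Fraction of stimuli carrying a third, unlabelled region
#'   as a central strip (default 0.05).
#' @param nonfg_halfwidth Half-width of that strip in patch degrees
#'   (default 0.3).
#' @param window_ms Spike-train window relative to stimulus onset, half-open
#'   (default `c(-100, 300)`).
#' @param seed Master seed for the generator.
#' @return A validated list of class `"fg_world_config"`.
#' @export
world_config <- function(n_stimuli = 105L, n_participants = 10L,
                         n_variants = 8L, n_repeats = 10L, n_neurons = 100L,
                         p_fg = 0.5, p_f_pref = 0.83,
                         theta_shape1 = 4.5, theta_shape2 = 5.5,
                         rt_base_ms = 450, rt_slope_ms = 200, rt_sigma = 0.2,
                         spont_hz = 10, evoked_hz = 20, gain = 0.45,
                         mod_dispersion = 2, mod_ramp_ms = 50,
                         mod_offset_ms = 175, mod_sustained = 0.15,
                         vis_latency_ms = 50,
                         onset_base_ms = 50, onset_slope_ms = 60,
                         nonfg_frac = 0.05, nonfg_halfwidth = 0.3,
                         window_ms = c(-100, 300), seed = 1L) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_stimuli >= 4, "n_stimuli must be >= 4")
  chk(n_participants >= 1, "n_participants must be >= 1")
  chk(n_variants >= 1, "n_variants must be >= 1")
  chk(n_repeats >= 1, "n_repeats must be >= 1")
  chk(n_neurons >= 1, "n_neurons must be >= 1")
  for (p in c("p_fg", "p_f_pref", "nonfg_frac")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must lie in [0, 1]"))
  }
  for (p in c("spont_hz", "evoked_hz", "gain", "mod_dispersion",
              "rt_sigma")) {
    chk(cfg[[p]] >= 0, paste(p, "must be >= 0"))
  }
  chk(theta_shape1 > 0 && theta_shape2 > 0, "theta shapes must be positive")
  chk(vis_latency_ms >= 0 && onset_base_ms >= vis_latency_ms,
      "onset_base_ms must be >= vis_latency_ms >= 0")
  chk(onset_slope_ms >= 0, "onset_slope_ms must be >= 0")
  chk(mod_ramp_ms >= 0, "mod_ramp_ms must be >= 0")
  chk(mod_offset_ms > onset_base_ms + mod_ramp_ms,
      "mod_offset_ms must exceed onset_base_ms + mod_ramp_ms")
  chk(mod_sustained >= 0 && mod_sustained <= 1,
      "mod_sustained must lie in [0, 1]")
  chk(length(window_ms) == 2 && window_ms[1] < 0 && window_ms[2] > 250,
      "window_ms must bracket [-100, 300)-style prestimulus and stimulus spans")
  chk(is.numeric(seed) && length(seed) == 1, "seed must be a single integer")
  if (length(problems) > 0) {
    stop("invalid world configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "fg_world_config")
}

#' Generate the latent world: stimuli, patches, neurons, placements
#'
#' Draws per-stimulus ambiguities and true figure sides, builds the
#' original/mirror patch pair for every stimulus (two-region masks split by a
#' vertical contour, with a central non-FG strip for a small fraction of
#' stimuli; the mirror patch swaps the two regions about the contour), and
#' draws neuron parameters (true modulation flag, preference, receptive-field
#' center and size) together with per-(neuron, stimulus) patch placements.
#' Everything downstream — trials, spike trains, grating maps — is a pure
#' function of this world and the config seed.
#'
#' @param config A [world_config()].
#' @return A list of class `"fg_world"` with tibbles `stimuli`, `patches`,
#'   `neurons`, `placements` and the `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "fg_world_config"))
  with_seed_if(derive_seed(config$seed, "world"), {
    ns <- config$n_stimuli
    stimuli <- tibble::tibble(
      stimulus_id = sprintf("s%03d", seq_len(ns)),
      theta = rbeta(ns, config$theta_shape1, config$theta_shape2),
      true_figure_region = sample(c("A", "B"), ns, replace = TRUE),
      nonfg = runif(ns) < config$nonfg_frac
    )
    stimuli$onset_ms <- config$onset_base_ms +
      config$onset_slope_ms * (1 - stimuli$theta)
    patches <- tidyr::crossing(stimulus_id = stimuli$stimulus_id,
                               kind = c("orig", "mirr")) |>
      dplyr::left_join(stimuli[, c("stimulus_id", "nonfg")],
                       by = "stimulus_id") |>
      dplyr::mutate(
        patch_id = paste(.data$stimulus_id, .data$kind, sep = "_"),
        contour_x = 0,
        halfwidth = ifelse(.data$nonfg, config$nonfg_halfwidth, 0),
        # region codes on each side of the contour; mirror swaps them
        left_region = ifelse(.data$kind == "orig", "A", "B"),
        right_region = ifelse(.data$kind == "orig", "B", "A"),
        xlim_lo = -3, xlim_hi = 3, ylim_lo = -3, ylim_hi = 3
      ) |>
      dplyr::select(-"nonfg")
    nn <- config$n_neurons
    n_fg <- round(nn * config$p_fg) # built fraction is exact by design
    is_fg <- sample(rep(c(TRUE, FALSE), c(n_fg, nn - n_fg)))
    pref <- ifelse(is_fg,
                   ifelse(runif(nn) < config$p_f_pref, "F", "G"),
                   NA_character_)
    neurons <- tibble::tibble(
      neuron_id = sprintf("n%03d", seq_len(nn)),
      is_fg = is_fg,
      preference = pref,
      gain = ifelse(is_fg, config$gain, 0),
      crf_x = runif(nn, -1.8, 1.8),
      crf_y = runif(nn, -1.8, 1.8),
      crf_sigma = runif(nn, 0.6, 1.2)
    )
    placements <- tidyr::crossing(neuron_id = neurons$neuron_id,
                                  stimulus_id = stimuli$stimulus_id) |>
      dplyr::mutate(offset_x = runif(dplyr::n(), -1, 1), offset_y = 0)
    structure(list(config = config, stimuli = stimuli, patches = patches,
                   neurons = neurons, placements = placements),
              class = "fg_world")
  })
}

#' @export
print.fg_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic figure-ground world: %d stimuli (%d patches), %d neurons (%d modulated), seed %d\n",
    nrow(x$stimuli), nrow(x$patches), nrow(x$neurons),
    sum(x$neurons$is_fg), x$config$seed))
  invisible(x)
}

#' Ground-truth figure/ground labels of the world
#'
#' The veridical label of a patch for a neuron is decided purely by geometry:
#' which region of the patch lies under the neuron's true receptive-field
#' center, given the per-(neuron, stimulus) placement, referred to the
#' stimulus's *true* figure side. These labels are exported for
#' parameter-recovery tests and are never consumed by the analysis stages,
#' which re-derive labels from fitted receptive fields and the
#' psychophysically determined figure side.
#'
#' @param world A [generate_world()] result.
#' @return Tibble `neuron_id`, `patch_id`, `label` (`"F"`, `"G"`, `"nonFG"`).
#' @export
true_labels <- function(world) {
  stopifnot(inherits(world, "fg_world"))
  grid <- dplyr::left_join(world$placements, world$patches,
                           by = "stimulus_id",
                           relationship = "many-to-many") |>
    dplyr::left_join(world$neurons[, c("neuron_id", "crf_x", "crf_y")],
                     by = "neuron_id") |>
    dplyr::left_join(world$stimuli[, c("stimulus_id", "true_figure_region")],
                     by = "stimulus_id")
  rel_x <- grid$crf_x - grid$offset_x
  region <- ifelse(rel_x < grid$contour_x, grid$left_region, grid$right_region)
  label <- ifelse(abs(rel_x - grid$contour_x) < grid$halfwidth, "nonFG",
                  ifelse(region == grid$true_figure_region, "F", "G"))
  tibble::tibble(neuron_id = grid$neuron_id, patch_id = grid$patch_id,
                 label = label)
}

#' Simulate the forced-choice psychophysics experiment
#'
#' Every observer judges every stimulus once per variant (original/mirror x
#' left-right reversal x presentation order). The chosen region is the true
#' figure side with probability `0.5 + 0.5 * theta`, independent of variant
#' (all variants share the stimulus's local properties). Reaction times are
#' lognormal with median `rt_base_ms + rt_slope_ms * (1 - theta)`; draws
#' breaching the 1000-ms deadline are redrawn, honouring the response window.
#'
#' @param world A [generate_world()] result.
#' @return Tibble of trials: `participant_id`, `stimulus_id`, `mirror`,
#'   `reversal`, `order`, `choice`, `rt_ms`.
#' @export
generate_psych_trials <- function(world) {
  stopifnot(inherits(world, "fg_world"))
  cfg <- world$config
  stopifnot(cfg$n_variants == 8L) # the 2 x 2 x 2 variant design
  with_seed_if(derive_seed(cfg$seed, "psych"), {
    grid <- tidyr::crossing(
      participant_id = sprintf("p%02d", seq_len(cfg$n_participants)),
      stimulus_id = world$stimuli$stimulus_id,
      mirror = c(FALSE, TRUE), reversal = c(FALSE, TRUE),
      order = c(FALSE, TRUE)
    ) |>
      dplyr::left_join(
        world$stimuli[, c("stimulus_id", "theta", "true_figure_region")],
        by = "stimulus_id")
    n <- nrow(grid)
    p_correct <- 0.5 + 0.5 * grid$theta
    toward <- runif(n) < p_correct
    other <- ifelse(grid$true_figure_region == "A", "B", "A")
    choice <- ifelse(toward, grid$true_figure_region, other)
    med <- cfg$rt_base_ms + cfg$rt_slope_ms * (1 - grid$theta)
    rt <- rlnorm(n, meanlog = log(med), sdlog = cfg$rt_sigma)
    while (any(rt > 1000)) {
      i <- which(rt > 1000)
      rt[i] <- rlnorm(length(i), meanlog = log(med[i]), sdlog = cfg$rt_sigma)
    }
    grid |>
      dplyr::mutate(choice = choice, rt_ms = rt) |>
      dplyr::select(-"theta", -"true_figure_region")
  })
}

#' Simulate spike trains by 1-ms grid thinning of an inhomogeneous Poisson rate
#'
#' Each (neuron, patch, repeat) trial draws at most one spike per 1-ms bin
#' with probability `rate(t) * 1 ms`. The rate is piecewise constant:
#' spontaneous before the visual latency, then the evoked rate; for modulated
#' neurons, patches whose true label matches the neuron's preference
#' additionally step up by `1 + gain * theta * m` at the stimulus's
#' modulation onset, where `m` is the neuron's per-stimulus
#' modulation-expression multiplier (unit-mean Gamma). Unmodulated neurons
#' never step. Spike times are the bin start in onset-relative ms; counting
#' windows elsewhere in the package are half-open, so a spike at exactly
#' +50 ms belongs to the stimulus window.
#'
#' @param world A [generate_world()] result.
#' @param neurons Optional character vector restricting which neurons to
#'   simulate (default: all).
#' @return A `data.table` with columns `neuron_id`, `patch_id`, `rep`,
#'   `t_ms`, one row per spike (zero-spike trials have no rows; the trial
#'   grid is implied by the world design).
#' @export
generate_spike_trains <- function(world, neurons = NULL) {
  stopifnot(inherits(world, "fg_world"))
  cfg <- world$config
  ids <- neurons %||% world$neurons$neuron_id
  labels <- true_labels(world)
  data.table::setDT(labels)
  bins <- seq.int(cfg$window_ms[1], cfg$window_ms[2] - 1L)
  nb <- length(bins)
  patch_info <- dplyr::left_join(
    world$patches[, c("patch_id", "stimulus_id")],
    world$stimuli[, c("stimulus_id", "theta", "onset_ms")],
    by = "stimulus_id")
  out <- vector("list", length(ids))
  with_seed_if(derive_seed(cfg$seed, "spikes"), {
    for (k in seq_along(ids)) {
      nid <- ids[k]
      nr <- world$neurons[world$neurons$neuron_id == nid, ]
      lab <- labels[labels$neuron_id == nid, ]
      lab_vec <- lab$label[match(patch_info$patch_id, lab$patch_id)]
      np <- nrow(patch_info)
      modulated <- nr$is_fg & !is.na(nr$preference) &
        !is.na(lab_vec) & lab_vec == nr$preference
      evoked_on <- bins >= cfg$vis_latency_ms
      base_rate <- ifelse(evoked_on, cfg$evoked_hz, cfg$spont_hz)
      spikes_k <- vector("list", np)
      for (j in seq_len(np)) {
        # per-ms Bernoulli probability, per repeat: modulated trials carry a
        # trial-specific unit-mean Gamma gain multiplier
        if (modulated[j]) {
          onset <- patch_info$onset_ms[j]
          rise <- if (cfg$mod_ramp_ms > 0) {
            pmin(1, pmax(0, (bins - onset) / cfg$mod_ramp_ms))
          } else {
            as.numeric(bins >= onset)
          }
          envelope <- ifelse(bins < cfg$mod_offset_ms, 1, cfg$mod_sustained)
          mod_profile <- cfg$evoked_hz * nr$gain * patch_info$theta[j] *
            rise * envelope
          m_rep <- if (cfg$mod_dispersion > 0) {
            stats::rgamma(cfg$n_repeats, shape = 1 / cfg$mod_dispersion,
                          scale = cfg$mod_dispersion)
          } else {
            rep(1, cfg$n_repeats)
          }
          pv <- pmin((rep(base_rate, cfg$n_repeats) +
                        as.vector(outer(mod_profile, m_rep))) / 1000, 1)
        } else {
          pv <- pmin(base_rate / 1000, 1)
        }
        draws <- rbinom(nb * cfg$n_repeats, 1L, pv)
        hit <- which(draws == 1L)
        if (length(hit) > 0) {
          spikes_k[[j]] <- data.table::data.table(
            patch_id = patch_info$patch_id[j],
            rep = (hit - 1L) %/% nb + 1L,
            t_ms = bins[(hit - 1L) %% nb + 1L])
        }
      }
      dt <- data.table::rbindlist(spikes_k)
      if (nrow(dt) > 0) data.table::set(dt, j = "neuron_id", value = nid)
      out[[k]] <- dt
    }
  })
  res <- data.table::rbindlist(out, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(res, c("neuron_id", "patch_id", "rep", "t_ms"))
  res[]
}

#' Simulate the grating-grid receptive-field mapping experiment
#'
#' Small grating patches on a 5 x 5 grid probe each neuron's receptive field;
#' the response map is the per-position mean firing rate over repeats, with
#' Poisson count noise, generated from the neuron's true isotropic Gaussian
#' receptive field on top of the spontaneous rate.
#'
#' @param world A [generate_world()] result.
#' @param grid_coords Numeric vector of grid positions per axis
#'   (default `seq(-2, 2, by = 1)`).
#' @param n_presentations Presentations per position (default 10).
#' @param count_window_ms Response-count window length (default 200 ms).
#' @return Tibble `neuron_id`, `x_deg`, `y_deg`, `mean_rate` (Hz).
#' @export
generate_grating_maps <- function(world, grid_coords = seq(-2, 2, by = 1),
                                  n_presentations = 10L,
                                  count_window_ms = 200) {
  stopifnot(inherits(world, "fg_world"))
  cfg <- world$config
  with_seed_if(derive_seed(cfg$seed, "gratings"), {
    g <- tidyr::crossing(neuron_id = world$neurons$neuron_id,
                         x_deg = grid_coords, y_deg = grid_coords) |>
      dplyr::left_join(world$neurons[, c("neuron_id", "crf_x", "crf_y",
                                         "crf_sigma")],
                       by = "neuron_id")
    rate <- cfg$spont_hz + cfg$evoked_hz *
      exp(-((g$x_deg - g$crf_x)^2 + (g$y_deg - g$crf_y)^2) /
            (2 * g$crf_sigma^2))
    lambda <- rate * count_window_ms / 1000
    counts <- rpois(nrow(g) * n_presentations,
                    rep(lambda, each = n_presentations))
    mean_counts <- colMeans(matrix(counts, nrow = n_presentations))
    tibble::tibble(neuron_id = g$neuron_id, x_deg = g$x_deg,
                   y_deg = g$y_deg,
                   mean_rate = mean_counts / (count_window_ms / 1000))
  })
}

#' Simulate the complete study
#'
#' Convenience wrapper generating the world plus all measured tables:
#' psychophysics trials, spike trains, grating maps, and the ground truth
#' (latent ambiguities, neuron parameters, true labels) that analysis stages
#' never see.
#'
#' @param config A [world_config()].
#' @return A list `world`, `trials`, `spikes`, `gratings`, `ground_truth`.
#' @export
simulate_study <- function(config) {
  world <- generate_world(config)
  list(world = world,
       trials = generate_psych_trials(world),
       spikes = generate_spike_trains(world),
       gratings = generate_grating_maps(world),
       ground_truth = list(stimuli = world$stimuli,
                           neurons = world$neurons,
                           labels = true_labels(world)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
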