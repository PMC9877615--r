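#' Read a forced-choice trial table
#'
#' Expects the CSV schema `participant_id,stimulus_id,mirror,reversal,order,
#' choice,rt_ms` (header required, UTF-8). Choices may be recorded either as
#' region codes in the un-reversed stimulus frame, or as screen sides
#' (`"left"`/`"right"`) which are resolved against the `reversal` flag and
#' the supplied side-to-region map — perceptual consistency is defined over
#' stimulus regions, not screen sides.
#'
#' @param path CSV path.
#' @param side_map Optional named character, e.g.
#'   `c(left = "A", right = "B")`, enabling screen-side resolution.
#' @return Trials tibble.
#' @export
read_psych_trials <- function(path, side_map = NULL) {
  trials <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  req <- c("participant_id", "stimulus_id", "mirror", "reversal", "order",
           "choice", "rt_ms")
  fail_if(list(
    "trial table must have the declared columns" =
      !all(req %in% names(trials)),
    "rt_ms must lie in (0, 1000]" =
      any(trials$rt_ms <= 0 | trials$rt_ms > 1000, na.rm = TRUE)
  ))
  if (!is.null(side_map) && all(trials$choice %in% names(side_map))) {
    side <- trials$choice
    flip <- as.logical(trials$reversal)
    other <- stats::setNames(rev(names(side_map)), names(side_map))
    resolved <- ifelse(flip, side_map[other[side]], side_map[side])
    trials$choice <- unname(resolved)
  }
  trials
}

#' Read a spike table (CSV or JSONL dialect)
#'
#' The CSV dialect holds one row per trial with `spike_times_ms` as a
#' semicolon-joined list; the JSONL dialect one JSON object per line with an
#' array. Both produce the same long in-memory table (one row per spike,
#' times sorted ascending); zero-spike trials are preserved through the
#' trial grid supplied to [spike_counts()], not through rows here.
#'
#' @param path File path; dialect chosen by extension (`.jsonl` vs `.csv`).
#' @return Long spike tibble `neuron_id`, `patch_id`, `rep`, `t_ms`.
#' @export
read_spike_table <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    recs <- lapply(readLines(path), jsonlite::fromJSON)
    rows <- dplyr::bind_rows(lapply(recs, function(r) {
      tibble::tibble(neuron_id = r$neuron_id, patch_id = r$patch_id,
                     rep = as.integer(r$rep),
                     t_ms = as.numeric(unlist(r$spike_times_ms)))
    }))
  } else {
    d <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(
                           spike_times_ms = readr::col_character()))
    dup <- duplicated(d[, c("neuron_id", "patch_id", "rep")])
    if (any(dup)) stop("duplicate (neuron, patch, repeat) trial rows: ",
                       sum(dup), call. = FALSE)
    d <- d[!is.na(d$spike_times_ms) & nzchar(d$spike_times_ms), ]
    times <- strsplit(d$spike_times_ms, ";", fixed = TRUE)
    rows <- tibble::tibble(
      neuron_id = rep(d$neuron_id, lengths(times)),
      patch_id = rep(d$patch_id, lengths(times)),
      rep = rep(as.integer(d$rep), lengths(times)),
      t_ms = as.numeric(unlist(times)))
  }
  dplyr::arrange(rows, .data$neuron_id, .data$patch_id, .data$rep,
                 .data$t_ms)
}

#' Write a spike table in the CSV dialect
#'
#' @param spikes Long spike table.
#' @param path Output CSV path.
#' @param trial_grid Optional trial grid so zero-spike trials are written as
#'   empty-time rows.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(spikes, path, trial_grid = NULL) {
  sp <- dplyr::as_tibble(spikes) |>
    dplyr::group_by(.data$neuron_id, .data$patch_id, .data$rep) |>
    dplyr::summarise(spike_times_ms = paste(sort(.data$t_ms), collapse = ";"),
                     .groups = "drop")
  if (!is.null(trial_grid)) {
    sp <- dplyr::left_join(trial_grid, sp,
                           by = c("neuron_id", "patch_id", "rep"))
    sp$spike_times_ms[is.na(sp$spike_times_ms)] <- ""
  }
  readr::write_csv(sp, path)
  invisible(path)
}

#' Load and cross-validate the analysis tables
#'
#' Reads the trial, spike, grating-map and patch/mask tables (plus optional
#' label, placement and ground-truth files), then enforces referential
#' integrity: every trial's stimulus must exist in the patch table, every
#' spike's patch must exist, and — when a label table is supplied — every
#' (neuron, patch) pair seen in the spikes must carry a label row. Violations
#' are itemised in the error.
#'
#' @param paths Named list with `trials`, `spikes`, `patches`, and optionally
#'   `gratings`, `labels`, `placements`.
#' @return A named list of validated tibbles.
#' @export
load_tables <- function(paths) {
  fail_if(list(
    "paths must name trials, spikes and patches files" =
      !all(c("trials", "spikes", "patches") %in% names(paths))
  ))
  out <- list(
    trials = read_psych_trials(paths$trials),
    spikes = read_spike_table(paths$spikes),
    patches = readr::read_csv(paths$patches, show_col_types = FALSE,
                              comment = "#"))
  for (nm in c("gratings", "labels", "placements")) {
    if (!is.null(paths[[nm]])) {
      out[[nm]] <- readr::read_csv(paths[[nm]], show_col_types = FALSE,
                                   comment = "#")
    }
  }
  problems <- character(0)
  orphan_stim <- setdiff(out$trials$stimulus_id, out$patches$stimulus_id)
  if (length(orphan_stim) > 0) {
    problems <- c(problems, paste("trial stimuli missing from patch table:",
                                  paste(orphan_stim, collapse = ", ")))
  }
  orphan_patch <- setdiff(out$spikes$patch_id, out$patches$patch_id)
  if (length(orphan_patch) > 0) {
    problems <- c(problems, paste("spike patches missing from patch table:",
                                  paste(orphan_patch, collapse = ", ")))
  }
  if (!is.null(out$labels)) {
    seen <- unique(out$spikes[, c("neuron_id", "patch_id")])
    lab_key <- paste(out$labels$neuron_id, out$labels$patch_id)
    miss <- !(paste(seen$neuron_id, seen$patch_id) %in% lab_key)
    if (any(miss)) {
      problems <- c(problems, paste(
        "spike (neuron, patch) pairs without a label row:",
        paste(paste(seen$neuron_id[miss], seen$patch_id[miss], sep = "/"),
              collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    stop("dataset integrity violations:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  message("loaded ", nrow(out$trials), " trials, ", nrow(out$spikes),
          " spikes, ", nrow(out$patches), " patches; 0 violations")
  out
}

#' Analysis constants of a full pipeline run
#'
#' Every constant defaults to the study's value and is overridable; the
#' resolved list is echoed into the output directory for provenance.
#'
#' @param group_k Single-cell group size (default 20).
#' @param group_k50 Population group size (default 50).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Permutation shuffles (default 10000).
#' @param p_values PNC population sizes (default `c(1, 10, 20, 30, 40)`).
#' @param pnc_repeats PNC repeats (default 200).
#' @param folds PNC cross-validation folds (default 5).
#' @param smooth_window_ms Latency smoothing window (default 50 ms).
#' @param fit_range Latency regression range (default `c(10, 150)` ms).
#' @param min_valid NC valid-trial exclusion bound (default 4).
#' @param min_patches PNC patch admission bound (default 40).
#' @param n_variants Psychophysics variants per participant (default 8).
#' @return A list of class `"fg_run_config"`.
#' @export
run_config <- function(group_k = 20L, group_k50 = 50L, alpha = 0.05,
                       n_perm = 10000L, p_values = c(1L, 10L, 20L, 30L, 40L),
                       pnc_repeats = 200L, folds = 5L,
                       smooth_window_ms = 50, fit_range = c(10, 150),
                       min_valid = 4L, min_patches = 40L, n_variants = 8L) {
  structure(as.list(environment()), class = "fg_run_config")
}

# Short provenance hash of the resolved configuration.
config_hash <- function(params, seed) {
  txt <- paste(yaml::as.yaml(unclass(params)), seed)
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

write_stamped_csv <- function(df, path, hash, seed) {
  writeLines(sprintf("# fgcons config_hash=%s seed=%d", hash, seed), path)
  suppressWarnings(readr::write_csv(df, path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' Run the full figure-ground consistency analysis
#'
#' Orchestrates the pipeline end to end: perceptual consistency and reaction
#' times, EASY/HARD grouping, receptive-field fitting and figure/ground
#' labelling, neuron screening, single-cell neural consistency with the
#' EASY-vs-HARD permutation comparison, population-based neural consistency
#' curves, PC-to-modulation-magnitude correlations, and modulation latencies
#' (raw and normalised). All randomness derives from `seed`; deterministic
#' stages (PC, labels, delta-R) do not depend on it. When `out_dir` is given,
#' the result tables, a machine-readable `headline.json`, an exclusion log
#' and the resolved configuration (with its hash and seed) are written there.
#'
#' @param data List with `trials`, `spikes`, `gratings`, `patches`,
#'   `n_repeats`, and optionally `placements` and `labels` (a label table
#'   bypasses receptive-field fitting).
#' @param params A [run_config()].
#' @param seed Master seed (default 1).
#' @param out_dir Optional output directory.
#' @return A list with all stage outputs and the `headline` list, invisibly
#'   when `out_dir` is written.
#' @export
run_report <- function(data, params = run_config(), seed = 1L,
                       out_dir = NULL) {
  stopifnot(inherits(params, "fg_run_config"))
  exclusions <- list()
  note_excl <- function(stage, id, rule) {
    exclusions[[length(exclusions) + 1L]] <<-
      tibble::tibble(stage = stage, id = id, rule = rule)
  }

  # --- psychophysics ---
  pc <- compute_pc(data$trials, n_variants = params$n_variants)
  rt <- compute_rt(data$trials)
  pc_tab <- dplyr::left_join(pc, rt, by = "stimulus_id")
  g20 <- rank_groups(pc_tab, params$group_k)
  g50 <- rank_groups(pc_tab, params$group_k50)
  pc_tab$group20 <- g20$group
  pc_tab$group50 <- g50$group
  pcsum <- pc_summary(pc_tab)
  pcrt <- pc_rt_relation(pc_tab)

  # --- labels ---
  if (!is.null(data$labels)) {
    label_table <- data$labels
    centers <- NULL
  } else {
    centers <- fit_crf_all(data$gratings)
    label_table <- assign_fg_labels(
      centers, data$patches,
      pc_tab[, c("stimulus_id", "figure_region")],
      placements = data$placements)
  }
  for (sid in pc_tab$stimulus_id[pc_tab$tie]) {
    note_excl("labels", sid, "tied psychophysics: figure side undefined")
  }

  # --- counts & screening ---
  neuron_ids <- sort(unique(data$spikes$neuron_id))
  grid <- trial_grid(data$patches, neuron_ids, data$n_repeats)
  stim_counts <- spike_counts(data$spikes, grid, 50, 250)
  pre_counts <- spike_counts(data$spikes, grid, -50, 50)
  screening <- screen_neurons(
    stim_counts, pre_counts, label_table,
    data$patches[, c("patch_id", "stimulus_id")], alpha = params$alpha)
  scr_sum <- screening_summary(screening)
  fg_ids <- screening$neuron_id[screening$fg_modulated]

  # --- single-cell NC (EASY/HARD, k = 20) ---
  patch_groups20 <- data$patches |>
    dplyr::inner_join(pc_tab[, c("stimulus_id", "group20")],
                      by = "stimulus_id") |>
    dplyr::filter(.data$group20 != "neither") |>
    dplyr::transmute(patch_id = .data$patch_id,
                     group = as.character(.data$group20))
  nc_table <- compute_nc_table(stim_counts, label_table, patch_groups20,
                               neuron_ids = fg_ids,
                               min_valid = params$min_valid)
  for (i in which(nc_table$excluded)) {
    note_excl("nc", paste(nc_table$neuron_id[i], nc_table$group[i]),
              nc_table$reason[i])
  }
  nc_cmp <- compare_nc_groups(nc_table, n_perm = params$n_perm,
                              seed = derive_seed(seed, "nc_perm"))

  # --- population decoding (EASY_50 / HARD_50, k = 50) ---
  pnc <- list()
  for (grp in c("EASY", "HARD")) {
    grp_patches <- data$patches$patch_id[
      data$patches$stimulus_id %in%
        pc_tab$stimulus_id[pc_tab$group50 == grp]]
    sets <- build_group_datasets(
      dplyr::filter(stim_counts, .data$neuron_id %in% fg_ids),
      label_table, grp_patches, min_patches = params$min_patches)
    excl <- attr(sets, "exclusions")
    for (i in seq_len(nrow(excl))) {
      note_excl("pnc", paste(excl$neuron_id[i], grp), excl$reason[i])
    }
    pnc[[grp]] <- pnc_sweep(
      sets, p_values = params$p_values[params$p_values <= length(sets)],
      n_repeats = params$pnc_repeats, folds = params$folds,
      seed = derive_seed(seed, paste0("pnc_", grp)),
      group = paste0(grp, "_50"))
  }
  pnc <- dplyr::bind_rows(pnc)

  # --- delta-R vs PC (paired-significant neurons) ---
  paired_ids <- screening$neuron_id[screening$fg_modulated_paired]
  trial_counts_lab <- stim_counts |>
    dplyr::left_join(label_table, by = c("neuron_id", "patch_id")) |>
    dplyr::left_join(data$patches[, c("patch_id", "stimulus_id")],
                     by = "patch_id")
  deltas <- list()
  for (nid in paired_ids) {
    prefn <- screening$preference_paired[screening$neuron_id == nid]
    if (is.na(prefn)) next
    dn <- trial_counts_lab[trial_counts_lab$neuron_id == nid,
                           c("stimulus_id", "patch_id", "label", "count")]
    deltas[[nid]] <- delta_r(dn, prefn)
  }
  drcor <- if (length(deltas) > 0) {
    pc_delta_r_correlation(pc_tab, deltas)
  } else NULL

  # --- modulation latency (EASY/HARD, k = 20) ---
  fg_prefs <- screening[screening$fg_modulated,
                        c("neuron_id", "preference")]
  latencies <- list()
  for (grp in c("EASY", "HARD")) {
    grp_patches <- data$patches$patch_id[
      data$patches$stimulus_id %in%
        pc_tab$stimulus_id[pc_tab$group20 == grp]]
    for (nrm in c(FALSE, TRUE)) {
      psth <- build_group_psth(data$spikes, grp_patches, label_table,
                               fg_prefs, data$n_repeats, normalize = nrm)
      latencies[[paste0(grp, if (nrm) "_norm" else "")]] <-
        modulation_latency(psth, params$smooth_window_ms, params$fit_range,
                           group = grp, normalized = nrm)
    }
  }

  headline <- list(
    pc_mean = pcsum$mean, pc_sd = pcsum$sd,
    pc_normality_p = pcsum$normality_p,
    pc_rt_pearson_r = pcrt$pearson_r, pc_rt_slope = pcrt$slope,
    frac_fg = scr_sum$frac_fg, frac_f_pref = scr_sum$frac_f_pref,
    overlap_paired = scr_sum$overlap_paired,
    nc_easy_mean = nc_cmp$mean_easy, nc_easy_sd = nc_cmp$sd_easy,
    nc_hard_mean = nc_cmp$mean_hard, nc_hard_sd = nc_cmp$sd_hard,
    nc_p = nc_cmp$p, nc_fraction_greater = nc_cmp$fraction_greater,
    pnc = pnc,
    mean_rho = if (!is.null(drcor)) drcor$summary$mean_rho else NA,
    rho_p = if (!is.null(drcor)) drcor$summary$p_onesided else NA,
    latency_easy_ms = latencies$EASY$latency_ms,
    latency_hard_ms = latencies$HARD$latency_ms,
    latency_easy_norm_ms = latencies$EASY_norm$latency_ms,
    latency_hard_norm_ms = latencies$HARD_norm$latency_ms)

  result <- list(pc_table = pc_tab, pc_summary = pcsum,
                 pc_rt = pcrt, crf = centers, labels = label_table,
                 screening = screening, screening_summary = scr_sum,
                 nc_table = nc_table, nc_comparison = nc_cmp, pnc = pnc,
                 delta_r_correlation = drcor, latencies = latencies,
                 exclusions = dplyr::bind_rows(exclusions),
                 headline = headline, seed = seed, params = params)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- config_hash(params, seed)
    cfg_echo <- c(unclass(params),
                  list(seed = seed, config_hash = h))
    yaml::write_yaml(cfg_echo, file.path(out_dir, "run_config.yaml"))
    pc_out <- pc_tab |>
      dplyr::transmute(.data$stimulus_id, .data$pc,
                       .data$rt_mean_ms, .data$figure_region,
                       group20 = as.character(.data$group20),
                       group50 = as.character(.data$group50))
    write_stamped_csv(pc_out, file.path(out_dir, "pc_table.csv"), h, seed)
    write_stamped_csv(screening, file.path(out_dir, "screening.csv"), h,
                      seed)
    write_stamped_csv(nc_table, file.path(out_dir, "nc_table.csv"), h, seed)
    write_stamped_csv(pnc, file.path(out_dir, "pnc.csv"), h, seed)
    if (!is.null(drcor)) {
      write_stamped_csv(drcor$per_neuron,
                        file.path(out_dir, "delta_r_correlations.csv"), h,
                        seed)
    }
    write_stamped_csv(result$exclusions,
                      file.path(out_dir, "exclusions.csv"), h, seed)
    lat_json <- lapply(latencies, function(l) {
      list(group = l$group, latency_ms = l$latency_ms, a0 = l$fit$a0,
           b0 = l$fit$b0, a1 = l$fit$a1, b1 = l$fit$b1, sse = l$fit$sse,
           valid = l$valid, normalized = l$normalized)
    })
    jsonlite::write_json(lat_json, file.path(out_dir, "latencies.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(c(list(config_hash = h, seed = seed),
                           headline),
                         file.path(out_dir, "headline.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(result))
  }
  result
}
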