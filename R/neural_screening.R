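#' Per-trial spike counts in a half-open window
#'
#' Counts spikes with `from <= t_ms < to` for every (neuron, patch, repeat)
#' trial of `grid`, including zero counts for trials that produced no spikes
#' (a spike table only records spikes, so the trial grid must be supplied by
#' the experimental design).
#'
#' @param spikes Spike table: `neuron_id`, `patch_id`, `rep`, `t_ms`.
#' @param grid Trial grid: `neuron_id`, `patch_id`, `rep`.
#' @param from,to Window bounds in onset-relative ms, half-open `[from, to)`.
#' @return Tibble `neuron_id`, `patch_id`, `rep`, `count`.
#' @export
spike_counts <- function(spikes, grid, from, to) {
  sp <- data.table::as.data.table(spikes)
  g <- data.table::as.data.table(grid[, c("neuron_id", "patch_id", "rep")])
  cnt <- sp[sp$t_ms >= from & sp$t_ms < to,
            list(count = .N), by = c("neuron_id", "patch_id", "rep")]
  res <- merge(g, cnt, by = c("neuron_id", "patch_id", "rep"),
               all.x = TRUE, sort = FALSE)
  res$count[is.na(res$count)] <- 0L
  tibble::as_tibble(res)
}

#' Build the trial grid implied by a patch table
#'
#' @param patches Patch table with `patch_id`.
#' @param neuron_ids Neuron identifiers.
#' @param n_repeats Repeats per patch.
#' @return Tibble `neuron_id`, `patch_id`, `rep`.
#' @export
trial_grid <- function(patches, neuron_ids, n_repeats) {
  tidyr::crossing(neuron_id = neuron_ids, patch_id = patches$patch_id,
                  rep = seq_len(n_repeats))
}

#' Fit an isotropic 2-D Gaussian receptive field to a grating response map
#'
#' Least-squares fit of
#' `baseline + amplitude * exp(-((x - cx)^2 + (y - cy)^2) / (2 sigma^2))`
#' to the mean firing rates on the grating grid. The receptive-field radius
#' is defined as 1 SD (`sigma`) of the fitted function, not its FWHM. The
#' Gaussian is isotropic with a baseline term: 25 grid points cannot support
#' a full covariance robustly.
#'
#' @param map Data frame `x_deg`, `y_deg`, `mean_rate` (typically 25 rows).
#' @return List of class `"crf_estimate"`: `center` (x, y in degrees),
#'   `radius_deg`, `baseline`, `amplitude`, `fit_sse`, `converged`,
#'   `in_grid` (center inside the tested grid's bounding box).
#' @export
fit_crf <- function(map) {
  fail_if(list(
    "map must contain x_deg, y_deg, mean_rate" =
      !all(c("x_deg", "y_deg", "mean_rate") %in% names(map)),
    "mean rates must be non-negative" = any(map$mean_rate < 0),
    "all-zero response map" = all(map$mean_rate == 0)
  ))
  i_max <- which.max(map$mean_rate)
  dx <- min(diff(sort(unique(map$x_deg))))
  start <- list(b = min(map$mean_rate),
                a = max(map$mean_rate) - min(map$mean_rate),
                cx = map$x_deg[i_max], cy = map$y_deg[i_max],
                s = dx)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mean_rate ~ b + a * exp(-((x_deg - cx)^2 + (y_deg - cy)^2) / (2 * s^2)),
      data = map, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(center = c(x = start$cx, y = start$cy),
                          radius_deg = abs(start$s), baseline = start$b,
                          amplitude = start$a, fit_sse = NA_real_,
                          converged = FALSE, in_grid = TRUE),
                     class = "crf_estimate"))
  }
  cf <- coef(fit)
  in_grid <- cf[["cx"]] >= min(map$x_deg) && cf[["cx"]] <= max(map$x_deg) &&
    cf[["cy"]] >= min(map$y_deg) && cf[["cy"]] <= max(map$y_deg)
  structure(list(center = c(x = cf[["cx"]], y = cf[["cy"]]),
                 radius_deg = abs(cf[["s"]]), baseline = cf[["b"]],
                 amplitude = cf[["a"]],
                 fit_sse = sum(residuals(fit)^2),
                 converged = TRUE, in_grid = in_grid),
            class = "crf_estimate")
}

#' @export
print.crf_estimate <- function(x, ...) {
  cat(sprintf(
    "CRF: center (%.3f, %.3f) deg, radius %.3f deg (1 SD), sse %.4g%s\n",
    x$center[1], x$center[2], x$radius_deg, x$fit_sse,
    if (!x$converged) " [not converged]"
    else if (!x$in_grid) " [center outside grid]" else ""))
  invisible(x)
}

#' Fit receptive fields for all neurons of a grating-map table
#'
#' @param gratings Tibble `neuron_id`, `x_deg`, `y_deg`, `mean_rate`.
#' @return Tibble `neuron_id`, `crf_x`, `crf_y`, `radius_deg`, `fit_sse`,
#'   `converged`, `in_grid`.
#' @export
fit_crf_all <- function(gratings) {
  maps <- split(gratings, gratings$neuron_id)
  rows <- lapply(names(maps), function(nid) {
    est <- fit_crf(maps[[nid]])
    tibble::tibble(neuron_id = nid, crf_x = est$center[["x"]],
                   crf_y = est$center[["y"]], radius_deg = est$radius_deg,
                   fit_sse = est$fit_sse, converged = est$converged,
                   in_grid = est$in_grid)
  })
  dplyr::bind_rows(rows)
}

#' Assign veridical figure/ground labels from a receptive-field center
#'
#' A patch is labelled `"F"` for a neuron when the neuron's receptive-field
#' center falls in the patch's figure region, `"G"` when it falls in the
#' ground region, and `"nonFG"` when it falls in an unlabelled third region,
#' outside the patch, or when the stimulus's figure side is undefined (tied
#' psychophysics). Labels therefore depend on the (neuron, patch) pair: the
#' same patch can carry different labels for different neurons, and a mirror
#' patch swaps the regions under a fixed center. Non-FG patches are excluded
#' from every downstream analysis.
#'
#' @param centers Tibble `neuron_id`, `crf_x`, `crf_y` (fitted or true
#'   receptive-field centers, in presentation coordinates).
#' @param patches Patch/mask table as in a generated world: `patch_id`,
#'   `stimulus_id`, `contour_x`, `halfwidth`, `left_region`, `right_region`,
#'   `xlim_lo`, `xlim_hi`, `ylim_lo`, `ylim_hi`.
#' @param figure_regions Tibble `stimulus_id`, `figure_region` (from
#'   [compute_pc()]; `NA` for ties).
#' @param placements Optional per-(neuron, stimulus) presentation offsets
#'   (`neuron_id`, `stimulus_id`, `offset_x`, `offset_y`); zero offsets when
#'   omitted.
#' @return Tibble `neuron_id`, `patch_id`, `label`.
#' @export
assign_fg_labels <- function(centers, patches, figure_regions,
                             placements = NULL) {
  fail_if(list(
    "centers must contain neuron_id, crf_x, crf_y" =
      !all(c("neuron_id", "crf_x", "crf_y") %in% names(centers)),
    "figure_regions must contain stimulus_id, figure_region" =
      !all(c("stimulus_id", "figure_region") %in% names(figure_regions))
  ))
  if (is.null(placements)) {
    placements <- tidyr::crossing(neuron_id = centers$neuron_id,
                                  stimulus_id = unique(patches$stimulus_id)) |>
      dplyr::mutate(offset_x = 0, offset_y = 0)
  }
  grid <- placements |>
    dplyr::left_join(patches, by = "stimulus_id",
                     relationship = "many-to-many") |>
    dplyr::left_join(centers[, c("neuron_id", "crf_x", "crf_y")],
                     by = "neuron_id") |>
    dplyr::left_join(figure_regions[, c("stimulus_id", "figure_region")],
                     by = "stimulus_id")
  rel_x <- grid$crf_x - grid$offset_x
  rel_y <- grid$crf_y - grid$offset_y
  outside <- rel_x < grid$xlim_lo | rel_x > grid$xlim_hi |
    rel_y < grid$ylim_lo | rel_y > grid$ylim_hi
  if (any(outside)) {
    warning(sum(outside), " receptive-field centers fall outside their ",
            "patch; labelled nonFG", call. = FALSE)
  }
  region <- ifelse(rel_x < grid$contour_x, grid$left_region,
                   grid$right_region)
  label <- ifelse(outside |
                    abs(rel_x - grid$contour_x) < grid$halfwidth |
                    is.na(grid$figure_region),
                  "nonFG",
                  ifelse(region == grid$figure_region, "F", "G"))
  tibble::tibble(neuron_id = grid$neuron_id, patch_id = grid$patch_id,
                 label = label)
}

#' Visual responsiveness of one neuron
#'
#' Compares per-trial firing rates between the prestimulus period
#' (-50 to +50 ms from onset) and the stimulus period (+50 to +250 ms) with a
#' t-test (paired across trials by default, since both windows come from the
#' same trial); the neuron is responsive when `p < alpha`.
#'
#' @param pre_counts,stim_counts Per-trial spike counts in the two windows,
#'   aligned trial-by-trial.
#' @param pre_dur_ms,stim_dur_ms Window durations used to convert counts to
#'   rates (defaults 100 and 200 ms).
#' @param alpha Significance level (default 0.05).
#' @param paired Paired t-test (default) or unpaired.
#' @return List `responsive`, `p`.
#' @export
test_responsiveness <- function(pre_counts, stim_counts, pre_dur_ms = 100,
                                stim_dur_ms = 200, alpha = 0.05,
                                paired = TRUE) {
  fail_if(list(
    "pre and stimulus counts must align trial-by-trial" =
      paired && length(pre_counts) != length(stim_counts),
    "need at least 2 trials" = length(stim_counts) < 2
  ))
  pre_rate <- pre_counts / pre_dur_ms
  stim_rate <- stim_counts / stim_dur_ms
  p <- tryCatch(t.test(stim_rate, pre_rate, paired = paired)$p.value,
                error = function(e) NA_real_)
  list(responsive = isTRUE(p < alpha), p = p)
}

#' Figure-ground modulation of one neuron (pooled F vs G trials)
#'
#' One-way ANOVA of stimulus-period spike counts grouped by the veridical F
#' vs G label, pooling all labelled patches and repeats; non-FG trials are
#' excluded. With two groups this equals the squared two-sample t statistic;
#' the repeated-measures error structure over repeats is not separately
#' modelled. Optionally the counts are Anscombe-transformed first (the
#' classification should not depend on the Poisson count distribution).
#'
#' @param counts Per-trial stimulus-window spike counts.
#' @param labels Per-trial labels (`"F"`, `"G"`, `"nonFG"`).
#' @param alpha Significance level (default 0.05).
#' @param transform `"none"` (default) or `"anscombe"`.
#' @return List `fg_modulated`, `preference` (`"F"` or `"G"`, the group with
#'   the larger mean), `p`.
#' @export
test_fg_modulation <- function(counts, labels, alpha = 0.05,
                               transform = c("none", "anscombe")) {
  transform <- match.arg(transform)
  keep <- !is.na(labels) & labels %in% c("F", "G")
  x <- counts[keep]
  g <- factor(labels[keep], levels = c("F", "G"))
  if (nlevels(droplevels(g)) < 2L) {
    stop("need trials in both the F and G groups", call. = FALSE)
  }
  if (transform == "anscombe") x <- anscombe(x)
  p <- tryCatch(oneway.test(x ~ g, var.equal = TRUE)$p.value,
                error = function(e) NA_real_)
  means <- tapply(x, g, mean)
  list(fg_modulated = isTRUE(p < alpha),
       preference = names(means)[which.max(means)],
       p = p)
}

#' Figure-ground modulation from original-mirror pairs
#'
#' Restricts the ANOVA to original-mirror pairs of a stimulus whose two
#' members carry *different* F/G labels for this neuron (pairs sharing one
#' label, e.g. when the receptive-field center lands on the same-labelled
#' region in both members, are excluded), then compares the trial counts of
#' the F members against the G members.
#'
#' @param counts Tibble `stimulus_id`, `patch_id`, `label`, `count`
#'   (trial-level rows for one neuron).
#' @param alpha Significance level (default 0.05).
#' @return List `fg_modulated_paired`, `preference`, `p`, `n_pairs`.
#' @export
test_fg_modulation_paired <- function(counts, alpha = 0.05) {
  fail_if(list(
    "counts must contain stimulus_id, patch_id, label, count" =
      !all(c("stimulus_id", "patch_id", "label", "count") %in% names(counts))
  ))
  pair_ok <- counts |>
    dplyr::distinct(.data$stimulus_id, .data$patch_id, .data$label) |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(
      valid = dplyr::n() == 2L && setequal(.data$label, c("F", "G")),
      .groups = "drop")
  valid_stim <- pair_ok$stimulus_id[pair_ok$valid]
  if (length(valid_stim) == 0L) {
    stop("no original-mirror pairs with differing F/G labels", call. = FALSE)
  }
  d <- dplyr::filter(counts, .data$stimulus_id %in% valid_stim)
  res <- test_fg_modulation(d$count, d$label, alpha = alpha)
  list(fg_modulated_paired = res$fg_modulated, preference = res$preference,
       p = res$p, n_pairs = length(valid_stim))
}

#' Screen all neurons for responsiveness and figure-ground modulation
#'
#' Runs, per neuron: the prestimulus-vs-stimulus responsiveness t-test, the
#' pooled F-vs-G ANOVA, and the original-mirror paired ANOVA. Responsiveness
#' is a precondition: a neuron counts as figure-ground modulated (pooled or
#' paired) only if it is also responsive. Preference is reported only for
#' modulated neurons.
#'
#' @param stim_counts Per-trial stimulus-window counts
#'   (`neuron_id`, `patch_id`, `rep`, `count`).
#' @param pre_counts Per-trial prestimulus-window counts, same grid.
#' @param label_table Labels per (neuron, patch) from [assign_fg_labels()].
#' @param patch_map Tibble `patch_id`, `stimulus_id`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per neuron: `neuron_id`, `responsive`,
#'   `p_resp`, `fg_modulated`, `preference`, `p_fg`, `fg_modulated_paired`,
#'   `preference_paired`, `p_paired`, `n_pairs`.
#' @export
screen_neurons <- function(stim_counts, pre_counts, label_table, patch_map,
                           alpha = 0.05) {
  key <- c("neuron_id", "patch_id", "rep")
  stim <- dplyr::arrange(stim_counts, !!!rlang::syms(key))
  pre <- dplyr::arrange(pre_counts, !!!rlang::syms(key))
  fail_if(list(
    "stim and pre count grids must match" =
      !identical(stim[key], pre[key])
  ))
  stim <- stim |>
    dplyr::left_join(label_table, by = c("neuron_id", "patch_id")) |>
    dplyr::left_join(patch_map[, c("patch_id", "stimulus_id")],
                     by = "patch_id")
  rows <- lapply(split(seq_len(nrow(stim)), stim$neuron_id), function(idx) {
    d <- stim[idx, ]
    resp <- test_responsiveness(pre$count[idx], d$count, alpha = alpha)
    fg <- tryCatch(test_fg_modulation(d$count, d$label, alpha = alpha),
                   error = function(e) list(fg_modulated = NA, preference =
                                              NA_character_, p = NA_real_))
    prd <- tryCatch(test_fg_modulation_paired(d, alpha = alpha),
                    error = function(e) list(fg_modulated_paired = NA,
                                             preference = NA_character_,
                                             p = NA_real_, n_pairs = 0L))
    tibble::tibble(
      neuron_id = d$neuron_id[1],
      responsive = resp$responsive, p_resp = resp$p,
      fg_modulated = resp$responsive & isTRUE(fg$fg_modulated),
      preference = ifelse(resp$responsive & isTRUE(fg$fg_modulated),
                          fg$preference, NA_character_),
      p_fg = fg$p,
      fg_modulated_paired = resp$responsive &
        isTRUE(prd$fg_modulated_paired),
      preference_paired = ifelse(
        resp$responsive & isTRUE(prd$fg_modulated_paired),
        prd$preference, NA_character_),
      p_paired = prd$p, n_pairs = prd$n_pairs)
  })
  dplyr::bind_rows(rows)
}

#' Summary counts of a screening run
#'
#' @param records Output of [screen_neurons()].
#' @return List with the numbers and fractions of responsive, figure-ground
#'   modulated (pooled and paired) and figure-preferring neurons, and the
#'   overlap between pooled and paired screening.
#' @export
screening_summary <- function(records) {
  n_fg <- sum(records$fg_modulated, na.rm = TRUE)
  n_paired <- sum(records$fg_modulated_paired, na.rm = TRUE)
  both <- sum(records$fg_modulated & records$fg_modulated_paired,
              na.rm = TRUE)
  list(
    n_neurons = nrow(records),
    n_responsive = sum(records$responsive, na.rm = TRUE),
    n_fg = n_fg,
    frac_fg = n_fg / nrow(records),
    n_f_pref = sum(records$preference == "F", na.rm = TRUE),
    frac_f_pref = if (n_fg > 0)
      sum(records$preference == "F", na.rm = TRUE) / n_fg else NA_real_,
    n_fg_paired = n_paired,
    overlap_paired = if (n_paired > 0) both / n_paired else NA_real_
  )
}
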