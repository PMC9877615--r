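#' Perceptual consistency per stimulus
#'
#' Perceptual consistency (PC) quantifies how consistently a region of a
#' stimulus is judged to be the figure across forced-choice trials and
#' participants:
#' \deqn{PC_i = \frac{1}{N_s} \sum_{j=1}^{N_s} \frac{\max(a_{ij}, b_{ij})}{N_v} \times 100}
#' where \eqn{a_{ij}} and \eqn{b_{ij}} are the numbers of answers given to the
#' two regions of stimulus \eqn{i} by participant \eqn{j}, \eqn{N_v} is the
#' number of variant trials per participant (8: original/mirror x left-right
#' reversal x presentation order) and \eqn{N_s} the number of participants.
#' PC ranges from 50 (chance) to 100 (perfect agreement) when every
#' participant completes all variants. Variants are pooled: PC never
#' distinguishes them, since all variants of a stimulus share its local image
#' properties.
#'
#' The majority-answered region across all trials and participants becomes the
#' stimulus's `figure_region`, which downstream supplies the veridical
#' figure/ground labels for neural analyses. An exact overall tie leaves
#' `figure_region` `NA` with `tie = TRUE` and a warning.
#'
#' @param trials Data frame of forced-choice trials with columns
#'   `participant_id`, `stimulus_id`, `choice` (one of the two region codes,
#'   in the un-reversed stimulus frame) and optionally `rt_ms`.
#' @param n_variants Expected trials per (participant, stimulus) (default 8).
#' @param strict If `TRUE` (default) every (participant, stimulus) cell must
#'   hold exactly `n_variants` trials, otherwise an error lists offenders.
#'   With `strict = FALSE` each participant's denominator is their own trial
#'   count (permissive mode for incomplete real datasets).
#' @return A tibble with one row per stimulus: `stimulus_id`, `pc`,
#'   `n_participants`, `n_variants`, `figure_region`, `tie`.
#' @export
compute_pc <- function(trials, n_variants = 8L, strict = TRUE) {
  req <- c("participant_id", "stimulus_id", "choice")
  fail_if(list(
    "trials must contain participant_id, stimulus_id, choice" =
      !all(req %in% names(trials))
  ))
  cell <- dplyr::count(trials, .data$stimulus_id, .data$participant_id,
                       name = "n_trials")
  if (strict) {
    bad <- dplyr::filter(cell, .data$n_trials != n_variants)
    if (nrow(bad) > 0) {
      stop("incomplete trial cells (expected ", n_variants, " trials): ",
           paste(sprintf("%s/%s=%d", bad$stimulus_id, bad$participant_id,
                         bad$n_trials), collapse = ", "),
           call. = FALSE)
    }
  }
  per_part <- trials |>
    dplyr::count(.data$stimulus_id, .data$participant_id, .data$choice) |>
    dplyr::group_by(.data$stimulus_id, .data$participant_id) |>
    dplyr::summarise(n_max = max(.data$n), n_tot = sum(.data$n),
                     .groups = "drop") |>
    dplyr::mutate(consistency = .data$n_max /
                    if (strict) n_variants else .data$n_tot)
  pooled <- trials |>
    dplyr::count(.data$stimulus_id, .data$choice) |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(
      figure_region = {
        m <- .data$n == max(.data$n)
        if (sum(m) > 1L) NA_character_ else as.character(.data$choice[m])
      },
      .groups = "drop") |>
    dplyr::mutate(tie = is.na(.data$figure_region))
  if (any(pooled$tie)) {
    warning("overall tie in region counts; figure_region undefined for: ",
            paste(pooled$stimulus_id[pooled$tie], collapse = ", "),
            call. = FALSE)
  }
  per_part |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(pc = 100 * mean(.data$consistency),
                     n_participants = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(n_variants = as.integer(n_variants)) |>
    dplyr::left_join(pooled, by = "stimulus_id")
}

#' Mean reaction time per stimulus
#'
#' Nested mean: the reaction times of each participant's variant trials are
#' averaged first, then averaged across participants (identical to the pooled
#' mean when all participants contribute equally many trials). Missing
#' reaction times are dropped from the inner mean with a message reporting the
#' count.
#'
#' @inheritParams compute_pc
#' @return A tibble `stimulus_id`, `rt_mean_ms`.
#' @export
compute_rt <- function(trials) {
  fail_if(list(
    "trials must contain participant_id, stimulus_id, rt_ms" =
      !all(c("participant_id", "stimulus_id", "rt_ms") %in% names(trials))
  ))
  n_missing <- sum(is.na(trials$rt_ms))
  if (n_missing > 0) {
    message(n_missing, " missing reaction times excluded from the inner mean")
  }
  trials |>
    dplyr::group_by(.data$stimulus_id, .data$participant_id) |>
    dplyr::summarise(rt = mean(.data$rt_ms, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(rt_mean_ms = mean(.data$rt), .groups = "drop")
}

#' Assign EASY / HARD stimulus groups by ranked perceptual consistency
#'
#' The `k` stimuli with the highest PC form the EASY (consistent) group and
#' the `k` lowest the HARD (ambiguous) group; the single-cell analysis uses
#' `k = 20`, the population analysis `k = 50`. Ranking is made deterministic
#' by breaking PC ties in ascending `stimulus_id`; a warning is emitted when a
#' tie straddles either group boundary.
#'
#' @param pc_table Output of [compute_pc()].
#' @param k Group size.
#' @return `pc_table` with an added factor column `group` taking values
#'   `"EASY"`, `"HARD"`, `"neither"`.
#' @export
rank_groups <- function(pc_table, k) {
  n <- nrow(pc_table)
  fail_if(list(
    "pc_table must contain stimulus_id and pc" =
      !all(c("stimulus_id", "pc") %in% names(pc_table)),
    "2k must not exceed the number of stimuli" = 2 * k > n
  ))
  ord <- order(pc_table$pc, pc_table$stimulus_id) # ascending pc, id tiebreak
  pc_sorted <- pc_table$pc[ord]
  if (k < n && (pc_sorted[k] == pc_sorted[k + 1] ||
                pc_sorted[n - k] == pc_sorted[n - k + 1])) {
    warning("PC ties straddle a group boundary; broken by ascending ",
            "stimulus_id", call. = FALSE)
  }
  group <- rep("neither", n)
  group[ord[seq_len(k)]] <- "HARD"
  group[ord[seq.int(n - k + 1L, n)]] <- "EASY"
  pc_table$group <- factor(group, levels = c("EASY", "HARD", "neither"))
  pc_table
}

#' Summary of the perceptual-consistency distribution
#'
#' Sample mean and SD of PC across stimuli, plus a one-sample
#' Kolmogorov-Smirnov p-value against a Gaussian with the sample moments
#' (estimated-moment comparison; approximate, since the moments are fitted to
#' the same data).
#'
#' @param pc_table Output of [compute_pc()] (needs `pc`; at least 3 stimuli).
#' @return A list `mean`, `sd`, `normality_p`, `degenerate`.
#' @export
pc_summary <- function(pc_table) {
  pc <- pc_table$pc
  fail_if(list("need at least 3 stimuli" = length(pc) < 3))
  m <- mean(pc); s <- sd(pc)
  if (s == 0) {
    return(list(mean = m, sd = s, normality_p = NA_real_, degenerate = TRUE))
  }
  p <- suppressWarnings(ks.test(pc, "pnorm", mean = m, sd = s)$p.value)
  list(mean = m, sd = s, normality_p = p, degenerate = FALSE)
}

#' Relation between perceptual consistency and reaction time
#'
#' Reaction times are standardised to z-scores across stimuli, then the
#' Pearson product-moment correlation with PC and the ordinary least-squares
#' slope of z(RT) on PC are computed. A negative correlation means stimuli
#' with more consistent figure-ground judgements are answered faster.
#'
#' @param pc_table Data frame with columns `pc` and `rt_mean_ms` (one row per
#'   stimulus; join [compute_pc()] and [compute_rt()]).
#' @return A list `pearson_r`, `slope`, `slope_p`, `n`.
#' @export
pc_rt_relation <- function(pc_table) {
  fail_if(list(
    "pc_table must contain pc and rt_mean_ms" =
      !all(c("pc", "rt_mean_ms") %in% names(pc_table)),
    "need at least 3 stimuli" = nrow(pc_table) < 3
  ))
  rt <- pc_table$rt_mean_ms
  if (sd(rt) == 0) stop("zero-variance reaction times", call. = FALSE)
  z <- as.numeric(scale(rt))
  fit <- lm(z ~ pc, data = data.frame(z = z, pc = pc_table$pc))
  list(pearson_r = cor(pc_table$pc, z),
       slope = unname(coef(fit)[2]),
       slope_p = summary(fit)$coefficients[2, 4],
       n = nrow(pc_table))
}
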