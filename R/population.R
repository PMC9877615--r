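#' Per-neuron learning dataset for population decoding
#'
#' For one neuron and one 50-stimulus group, builds the 100-row dataset
#' pairing each patch (50 stimuli x original/mirror) with the sum of its
#' spike counts over the repeats and its veridical F/G label. Non-FG patches
#' are dropped before the row count is assessed. A neuron is admitted only if
#' spikes were observed (summed count > 0) in more than `min_patches` patches
#' of *each* class; sparser neurons are excluded so that the pooled
#' population matrices carry no missing data.
#'
#' @param counts Per-trial stimulus-window counts for one neuron restricted
#'   to the group's patches: `patch_id`, `rep`, `count`.
#' @param labels Tibble `patch_id`, `label` for this neuron.
#' @param neuron_id Identifier copied into the output.
#' @param min_patches Admission bound (default 40: excluded when spikes are
#'   observed in `<= 40` patches of either class).
#' @return List of class `"neuron_dataset"`: `neuron_id`, `rows` (tibble
#'   `patch_id`, `sum_count`, `label`), `admitted`, `reason`.
#' @export
build_neuron_dataset <- function(counts, labels, neuron_id = NA_character_,
                                 min_patches = 40L) {
  rows <- counts |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(sum_count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(labels, by = "patch_id") |>
    dplyr::filter(.data$label %in% c("F", "G"))
  n_active <- rows |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = sum(.data$sum_count > 0), .groups = "drop")
  ok_classes <- c("F", "G") %in% n_active$label &
    c(sum(n_active$n[n_active$label == "F"]),
      sum(n_active$n[n_active$label == "G"])) > min_patches
  if (!all(ok_classes)) {
    return(structure(list(neuron_id = neuron_id, rows = rows,
                          admitted = FALSE,
                          reason = sprintf(
                            "spikes observed in <= %d patches for %s",
                            min_patches,
                            paste(c("F", "G")[!ok_classes], collapse = " and "))),
                     class = "neuron_dataset"))
  }
  structure(list(neuron_id = neuron_id, rows = rows, admitted = TRUE,
                 reason = NA_character_),
            class = "neuron_dataset")
}

#' Build the per-neuron datasets for every neuron of a group
#'
#' @param stim_counts Per-trial counts (`neuron_id`, `patch_id`, `rep`,
#'   `count`).
#' @param label_table Labels per (neuron, patch).
#' @param group_patches Character vector of the group's patch ids.
#' @param min_patches See [build_neuron_dataset()].
#' @return List of admitted `"neuron_dataset"` objects; excluded neurons are
#'   reported via the `"exclusions"` attribute (tibble `neuron_id`,
#'   `reason`).
#' @export
build_group_datasets <- function(stim_counts, label_table, group_patches,
                                 min_patches = 40L) {
  d <- dplyr::filter(stim_counts, .data$patch_id %in% group_patches)
  ids <- unique(d$neuron_id)
  sets <- lapply(ids, function(nid) {
    build_neuron_dataset(
      d[d$neuron_id == nid, c("patch_id", "rep", "count")],
      label_table[label_table$neuron_id == nid, c("patch_id", "label")],
      neuron_id = nid, min_patches = min_patches)
  })
  admitted <- vapply(sets, function(s) s$admitted, logical(1))
  excl <- tibble::tibble(
    neuron_id = vapply(sets[!admitted], function(s) s$neuron_id, character(1)),
    reason = vapply(sets[!admitted], function(s) s$reason, character(1)))
  structure(sets[admitted], exclusions = excl)
}

#' Assemble a label-aligned population matrix
#'
#' Chooses `p` neurons at random without repetition, and for each neuron
#' independently samples `n_per_class` F-labelled and `n_per_class`
#' G-labelled of its patch rows without repetition; the summed counts are
#' column-bound into an `2 n_per_class x p` matrix whose row labels are
#' position-aligned (first `n_per_class` rows F, the rest G). Rows are
#' label-aligned pseudo-trials — the neurons sampled their patches
#' independently, and no patch identity enters the feature set, so
#' classification can rest only on the figure-ground information. A
#' `shared_patches` mode instead draws one patch sample used by every neuron
#' (sensitivity analysis; requires identical label layouts across neurons,
#' so it is limited to worlds without label heterogeneity).
#'
#' When a class has fewer than `n_per_class` rows (non-FG exclusions), all
#' available rows are used and the imbalance is reported via a warning.
#'
#' @param datasets List of admitted [build_neuron_dataset()] objects.
#' @param p Number of neurons to pool.
#' @param n_per_class Patches sampled per class per neuron (default 40).
#' @param shared_patches Draw one common patch sample (default `FALSE`).
#' @param seed Optional seed.
#' @return List `x` (matrix, neurons in columns), `y` (factor `"F"`/`"G"`),
#'   `neurons` (chosen ids).
#' @export
assemble_population <- function(datasets, p, n_per_class = 40L,
                                shared_patches = FALSE, seed = NULL) {
  if (p > length(datasets)) {
    stop("p = ", p, " exceeds the admissible neuron pool (",
         length(datasets), ")", call. = FALSE)
  }
  with_seed_if(seed, {
    chosen <- sample.int(length(datasets), p)
    shared_idx <- NULL
    cols <- vector("list", p)
    y <- NULL
    for (k in seq_len(p)) {
      rows <- datasets[[chosen[k]]]$rows
      f_idx <- which(rows$label == "F")
      g_idx <- which(rows$label == "G")
      nf <- min(n_per_class, length(f_idx))
      ng <- min(n_per_class, length(g_idx))
      if (nf < n_per_class || ng < n_per_class) {
        warning("neuron ", datasets[[chosen[k]]]$neuron_id,
                ": only ", nf, " F / ", ng, " G patches available",
                call. = FALSE)
      }
      if (shared_patches) {
        if (is.null(shared_idx)) {
          shared_idx <- list(f = sample(f_idx, nf), g = sample(g_idx, ng))
        }
        take <- c(shared_idx$f, shared_idx$g)
      } else {
        take <- c(sample(f_idx, nf), sample(g_idx, ng))
      }
      cols[[k]] <- rows$sum_count[take]
      if (is.null(y)) y <- rows$label[take]
    }
    list(x = do.call(cbind, cols), y = factor(y, levels = c("F", "G")),
         neurons = vapply(chosen, function(i) datasets[[i]]$neuron_id,
                          character(1)))
  })
}

# Stratified k-fold index assignment: each class is split evenly.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fit an RBF SVM and score accuracy on held-out data, guarding degenerate
# constant-feature inputs with a majority-vote fallback.
svm_fold_accuracy <- function(x_train, y_train, x_test, y_test, cost, gamma) {
  keep <- which(apply(x_train, 2, var) > 0)
  if (length(keep) == 0L) {
    maj <- names(which.max(table(y_train)))
    return(mean(y_test == maj))
  }
  fit <- e1071::svm(x_train[, keep, drop = FALSE], y_train,
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = TRUE)
  mean(predict(fit, x_test[, keep, drop = FALSE]) == y_test)
}

#' Population-based neural consistency
#'
#' PNC is the cross-validated correct rate of an RBF-kernel SVM classifying
#' figure vs ground from pooled spike counts:
#' `PNC = 100 * n_test_correct / n_test`. Each repeat draws a fresh neuron
#' sample and patch sample via [assemble_population()], selects the SVM
#' hyperparameters by grid search on training patches (a 2-fold inner split
#' of the first fold's training set; the chosen pair is applied to all
#' folds of the repeat), runs stratified 5-fold cross-validation (64
#' training / 16 test patches in the full design) and records the mean test
#' accuracy; the PNC of a condition aggregates `n_repeats` repeats.
#'
#' @param datasets List of admitted [build_neuron_dataset()] objects.
#' @param p Number of neurons to pool.
#' @param n_repeats Repeats (default 200).
#' @param folds Cross-validation folds (default 5).
#' @param n_per_class Patches per class per neuron (default 40).
#' @param cost_grid,gamma_scale_grid Hyperparameter grids; `gamma` is
#'   `gamma_scale / p` so the grid tracks the feature count (defaults
#'   `2^c(-2, 0, 2)` and `2^c(-6, -4, -2)`). The grid is biased toward
#'   smooth, near-linear kernels: population matrices offer only 64
#'   training patches in up to 40 dimensions, where flexible boundaries
#'   overfit.
#' @param shared_patches See [assemble_population()].
#' @param seed Optional seed; each repeat derives its own stream.
#' @param group Group tag copied into the output.
#' @return One-row tibble: `group`, `p`, `pnc_mean`, `pnc_sd`, `n_repeats`.
#' @export
compute_pnc <- function(datasets, p, n_repeats = 200L, folds = 5L,
                        n_per_class = 40L, cost_grid = 2^c(-2, 0, 2),
                        gamma_scale_grid = 2^c(-6, -4, -2),
                        shared_patches = FALSE, seed = NULL,
                        group = NA_character_) {
  if (length(datasets) == 0L) stop("empty admissible neuron pool",
                                   call. = FALSE)
  acc <- with_seed_if(seed, {
    vapply(seq_len(n_repeats), function(rep_i) {
      pop <- assemble_population(datasets, p, n_per_class = n_per_class,
                                 shared_patches = shared_patches)
      x <- pop$x; y <- pop$y
      fold <- stratified_folds(y, folds)
      # hyperparameter selection on the first fold's training patches
      tr <- which(fold != 1L)
      inner <- stratified_folds(y[tr], 2L)
      grid <- expand.grid(cost = cost_grid, gscale = gamma_scale_grid)
      p_eff <- max(1L, ncol(x))
      gscore <- vapply(seq_len(nrow(grid)), function(gi) {
        mean(vapply(1:2, function(f) {
          it <- tr[inner != f]; iv <- tr[inner == f]
          svm_fold_accuracy(x[it, , drop = FALSE], y[it],
                            x[iv, , drop = FALSE], y[iv],
                            grid$cost[gi], grid$gscale[gi] / p_eff)
        }, numeric(1)))
      }, numeric(1))
      best <- grid[which.max(gscore), ]
      mean(vapply(seq_len(folds), function(f) {
        it <- which(fold != f); iv <- which(fold == f)
        svm_fold_accuracy(x[it, , drop = FALSE], y[it],
                          x[iv, , drop = FALSE], y[iv],
                          best$cost, best$gscale / p_eff)
      }, numeric(1)))
    }, numeric(1))
  })
  tibble::tibble(group = group, p = as.integer(p),
                 pnc_mean = 100 * mean(acc), pnc_sd = 100 * sd(acc),
                 n_repeats = as.integer(n_repeats))
}

#' PNC as a function of population size
#'
#' Sweeps [compute_pnc()] over the requested neuron counts (the study design
#' uses 1, 10, 20, 30 and 40).
#'
#' @inheritParams compute_pnc
#' @param p_values Neuron counts (default `c(1, 10, 20, 30, 40)`).
#' @return Tibble with one row per `p`.
#' @export
pnc_sweep <- function(datasets, p_values = c(1L, 10L, 20L, 30L, 40L),
                      n_repeats = 200L, folds = 5L, n_per_class = 40L,
                      seed = NULL, group = NA_character_, ...) {
  dplyr::bind_rows(lapply(seq_along(p_values), function(i) {
    compute_pnc(datasets, p_values[i], n_repeats = n_repeats, folds = folds,
                n_per_class = n_per_class,
                seed = if (is.null(seed)) NULL
                       else derive_seed(seed, paste0("pnc_p", p_values[i])),
                group = group, ...)
  }))
}
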