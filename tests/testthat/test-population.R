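make_counts_for_dataset <- function(n_stim = 50L, f_rate = 6, g_rate = 4,
                                    n_rep = 10L) {
  labels <- tibble::tibble(
    patch_id = sprintf("s%03d_%s", rep(seq_len(n_stim), each = 2),
                       c("orig", "mirr")),
    label = rep(c("F", "G"), n_stim))
  counts <- tidyr::crossing(patch_id = labels$patch_id, rep = seq_len(n_rep)) |>
    dplyr::left_join(labels, by = "patch_id")
  counts$count <- rpois(nrow(counts),
                        ifelse(counts$label == "F", f_rate, g_rate))
  list(counts = counts, labels = labels)
}

test_that("per-neuron datasets sum repeats into 100 labelled patch rows and
           exclude sparse neurons", {
  set.seed(2)
  d <- make_counts_for_dataset()
  ds <- build_neuron_dataset(d$counts[, c("patch_id", "rep", "count")],
                             d$labels, neuron_id = "n1")
  expect_true(ds$admitted)
  expect_equal(nrow(ds$rows), 100)
  sums <- d$counts |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(s = sum(.data$count))
  expect_equal(ds$rows$sum_count[match(sums$patch_id, ds$rows$patch_id)],
               sums$s)

  # neuron silent on 65 of its 50 F patches cannot happen; silence on enough
  # F patches to leave <= 40 active triggers exclusion
  sparse <- d$counts
  silent_f <- d$labels$patch_id[d$labels$label == "F"][1:15]
  sparse$count[sparse$patch_id %in% silent_f] <- 0L
  dss <- build_neuron_dataset(sparse[, c("patch_id", "rep", "count")],
                              d$labels, neuron_id = "n2")
  expect_false(dss$admitted)
  expect_match(dss$reason, "F")
})

test_that("nonFG patches are dropped before the row count and sampling warns
           about the imbalance", {
  set.seed(6)
  d <- make_counts_for_dataset()
  labels <- d$labels
  labels$label[labels$label == "F"][1:12] <- "nonFG"
  ds <- build_neuron_dataset(d$counts[, c("patch_id", "rep", "count")],
                             labels, neuron_id = "n1", min_patches = 30L)
  expect_equal(nrow(ds$rows), 88)
  expect_warning(pop <- assemble_population(list(ds), 1, seed = 3),
                 "38 F")
  expect_equal(sum(pop$y == "F"), 38)
})

test_that("population assembly is label-aligned, seed-deterministic, and
           bounded by the pool size", {
  set.seed(10)
  sets <- lapply(1:5, function(i)
    make_gaussian_dataset(paste0("n", i), d_prime = 1))
  pop <- assemble_population(sets, 1, seed = 11)
  expect_equal(dim(pop$x), c(80, 1))
  expect_equal(as.vector(table(pop$y)), c(40, 40))
  pop2 <- assemble_population(sets, 3, seed = 12)
  expect_identical(assemble_population(sets, 3, seed = 12), pop2)
  expect_error(assemble_population(sets, 6), "exceeds")
})

test_that("PNC is near ceiling for separable neurons and at chance for
           label-independent neurons (cross-validation removes the in-sample
           lift)", {
  set.seed(19)
  sep <- lapply(1:3, function(i) make_gaussian_dataset(paste0("n", i), 8))
  res <- compute_pnc(sep, 1, n_repeats = 10, seed = 2)
  expect_gte(res$pnc_mean, 95)

  null <- lapply(1:6, function(i) make_gaussian_dataset(paste0("n", i), 0))
  res0 <- compute_pnc(null, 4, n_repeats = 20, seed = 3)
  expect_gt(res0$pnc_mean, 44)
  expect_lt(res0$pnc_mean, 56)
})

test_that("shuffling the labels of informative neurons drives PNC to
           chance", {
  set.seed(26)
  sets <- lapply(1:6, function(i) make_gaussian_dataset(paste0("n", i), 1.5))
  # expectation over fresh shuffles: a single fixed shuffle is one null
  # dataset whose cross-validated accuracy still varies by several points
  means <- replicate(8, {
    shuffled <- lapply(sets, function(s) {
      s$rows$label <- sample(s$rows$label)
      s
    })
    compute_pnc(shuffled, 6, n_repeats = 5,
                seed = sample.int(1e6, 1))$pnc_mean
  })
  expect_gt(mean(means), 47)
  expect_lt(mean(means), 53)
})

test_that("PNC grows with the number of pooled informative neurons", {
  set.seed(33)
  sets <- lapply(1:12, function(i) make_gaussian_dataset(paste0("n", i), 0.6))
  sweep <- pnc_sweep(sets, p_values = c(1, 4, 12), n_repeats = 25, seed = 9)
  expect_equal(nrow(sweep), 3)
  # non-decreasing within twice the Monte-Carlo standard error
  se <- sweep$pnc_sd / sqrt(sweep$n_repeats)
  expect_true(all(diff(sweep$pnc_mean) > -2 * max(se)))
  expect_gt(sweep$pnc_mean[3], sweep$pnc_mean[1] + 5)
})

test_that("degenerate all-constant features fall back to majority vote", {
  flat <- lapply(1:2, function(i) {
    s <- make_gaussian_dataset(paste0("n", i), 0)
    s$rows$sum_count <- 5
    s
  })
  res <- compute_pnc(flat, 2, n_repeats = 5, seed = 1)
  expect_gt(res$pnc_mean, 40)
  expect_lt(res$pnc_mean, 60)
})
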