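gauss_map <- function(cx, cy, sigma, amp = 20, base = 5,
                      coords = seq(-2, 2, by = 1)) {
  g <- expand.grid(x_deg = coords, y_deg = coords)
  g$mean_rate <- base + amp *
    exp(-((g$x_deg - cx)^2 + (g$y_deg - cy)^2) / (2 * sigma^2))
  tibble::as_tibble(g)
}

test_that("receptive-field fit recovers a noiseless Gaussian to high
           precision, with radius = 1 SD (not FWHM)", {
  est <- fit_crf(gauss_map(1.5, -2, 1))
  expect_equal(unname(est$center["x"]), 1.5, tolerance = 1e-6)
  expect_equal(unname(est$center["y"]), -2, tolerance = 1e-6)
  expect_equal(est$radius_deg, 1, tolerance = 1e-6) # sigma, not 2.355 sigma
  expect_lt(est$fit_sse, 1e-10)
  expect_true(est$converged)
  expect_error(fit_crf(dplyr::mutate(gauss_map(0, 0, 1), mean_rate = 0)),
               "all-zero")
})

test_that("receptive-field centers are recovered within half a degree from
           Poisson-noisy maps", {
  set.seed(14)
  errs <- replicate(10, {
    cx <- runif(1, -1.5, 1.5); cy <- runif(1, -1.5, 1.5)
    m <- gauss_map(cx, cy, runif(1, 0.7, 1.1))
    m$mean_rate <- rpois(nrow(m), m$mean_rate * 2) / 2 # 10 reps, 200 ms
    est <- fit_crf(m)
    sqrt(sum((est$center - c(cx, cy))^2))
  })
  expect_gte(sum(errs < 0.5), 9)
})

test_that("figure/ground labels follow the region under the center, swap on
           the mirror patch, and fall back to nonFG", {
  patches <- tibble::tibble(
    stimulus_id = "s001", kind = c("orig", "mirr"),
    patch_id = c("s001_orig", "s001_mirr"),
    contour_x = 0, halfwidth = c(0, 0),
    left_region = c("A", "B"), right_region = c("B", "A"),
    xlim_lo = -3, xlim_hi = 3, ylim_lo = -3, ylim_hi = 3)
  figs <- tibble::tibble(stimulus_id = "s001", figure_region = "A")
  centers <- tibble::tibble(neuron_id = c("n1", "n2"),
                            crf_x = c(-1, 1), crf_y = 0)
  lab <- assign_fg_labels(centers, patches, figs)
  get <- function(n, p) lab$label[lab$neuron_id == n & lab$patch_id == p]
  expect_equal(get("n1", "s001_orig"), "F") # left = A = figure
  expect_equal(get("n1", "s001_mirr"), "G") # mirror swaps regions
  expect_equal(get("n2", "s001_orig"), "G")
  expect_equal(get("n2", "s001_mirr"), "F")

  # geometric oracle on a grid of centers: mirror always flips F/G
  grid_centers <- tibble::tibble(neuron_id = sprintf("g%02d", 1:20),
                                 crf_x = seq(-2.5, 2.5, length.out = 20),
                                 crf_y = 0)
  lab2 <- assign_fg_labels(grid_centers, patches, figs) |>
    tidyr::pivot_wider(names_from = "patch_id", values_from = "label")
  fg <- lab2[lab2$s001_orig %in% c("F", "G"), ]
  expect_true(all(fg$s001_orig != fg$s001_mirr))

  # third-region strip and tied psychophysics produce nonFG
  strip <- dplyr::mutate(patches, halfwidth = 0.5)
  labs <- assign_fg_labels(tibble::tibble(neuron_id = "n3", crf_x = 0.2,
                                          crf_y = 0), strip, figs)
  expect_true(all(labs$label == "nonFG"))
  tied <- tibble::tibble(stimulus_id = "s001",
                         figure_region = NA_character_)
  labt <- assign_fg_labels(centers, patches, tied)
  expect_true(all(labt$label == "nonFG"))
  expect_warning(
    assign_fg_labels(tibble::tibble(neuron_id = "n4", crf_x = 5,
                                    crf_y = 0), patches, figs),
    "outside")
})

test_that("responsiveness testing is calibrated under the null and powered
           for a threefold rate increase", {
  set.seed(31)
  null_hits <- replicate(200, {
    pre <- rpois(420, 2); stim <- rpois(420, 4) # same 20 Hz rate, 100/200 ms
    test_responsiveness(pre, stim)$responsive
  })
  expect_lt(mean(null_hits), 0.11)
  driven <- replicate(50, {
    pre <- rpois(420, 2); stim <- rpois(420, 12) # 20 -> 60 Hz
    test_responsiveness(pre, stim)$responsive
  })
  expect_true(all(driven))
})

test_that("figure-ground ANOVA detects a 1.5x rate difference with the right
           preference, agrees under the Anscombe transform, and is calibrated
           under the null", {
  set.seed(8)
  labels <- rep(c("F", "G"), each = 500)
  counts <- c(rpois(500, 6), rpois(500, 4))
  raw <- test_fg_modulation(counts, labels)
  expect_true(raw$fg_modulated)
  expect_equal(raw$preference, "F")
  expect_true(test_fg_modulation(counts, labels,
                                 transform = "anscombe")$fg_modulated)

  null_hits <- replicate(200, {
    test_fg_modulation(rpois(200, 4), rep(c("F", "G"), 100))$fg_modulated
  })
  expect_lt(mean(null_hits), 0.11)
  expect_error(test_fg_modulation(rpois(10, 4), rep("F", 10)), "both")
})

test_that("paired screening uses only mixed-label original-mirror pairs and
           errors when none exist", {
  set.seed(4)
  d <- tibble::tibble(
    stimulus_id = rep(sprintf("s%02d", 1:40), each = 20),
    patch_id = rep(sprintf("s%02d_%s", rep(1:40, each = 2),
                           c("orig", "mirr")), each = 10),
    label = rep(rep(c("F", "G"), 40), each = 10))
  d$count <- rpois(nrow(d), ifelse(d$label == "F", 6, 4))
  res <- test_fg_modulation_paired(d)
  expect_true(res$fg_modulated_paired)
  expect_equal(res$n_pairs, 40)

  same <- dplyr::mutate(d, label = "F")
  expect_error(test_fg_modulation_paired(same), "differing")
})
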