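test_that("permutation p-value uses the add-one convention and hits its floor
           on fully separated samples", {
  res <- permutation_test(rnorm(200, 10), rnorm(200, 0), n_perm = 1000,
                          alternative = "greater", seed = 1)
  expect_equal(res$p, 1 / 1001)
  expect_gt(res$observed, 8)

  # 4 + 4 miniature: exhaustive enumeration confirms no relabelling can
  # reach the observed difference when the samples are disjointly separated
  x <- c(10, 11, 12, 13); y <- c(0, 1, 2, 3)
  z <- c(x, y)
  combos <- utils::combn(8, 4)
  stats <- apply(combos, 2, function(i) mean(z[i]) - mean(z[-i]))
  expect_equal(sum(stats >= mean(x) - mean(y)), 1) # only the identity split
  # Monte-Carlo p approximates the exhaustive one-in-70 probability
  p_mini <- permutation_test(x, y, n_perm = 2000, seed = 2)$p
  expect_lt(abs(p_mini - 1 / 70), 0.01)
})

test_that("degenerate identical samples give p = 1 with a warning", {
  expect_warning(res <- permutation_test(c(3, 3, 3, 3), c(3, 3, 3, 3),
                                         n_perm = 99),
                 "identical")
  expect_equal(res$p, 1)
})

test_that("permutation p is (stochastically) invariant under swapping samples
           and flipping the alternative", {
  set.seed(42)
  x <- rnorm(25, 0.4); y <- rnorm(25)
  p1 <- permutation_test(x, y, n_perm = 4000, alternative = "greater",
                         seed = 7)$p
  p2 <- permutation_test(y, x, n_perm = 4000, alternative = "less",
                         seed = 8)$p
  expect_lt(abs(p1 - p2), 0.03)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(11)
  ps <- replicate(300, {
    permutation_test(rnorm(15), rnorm(15), n_perm = 199,
                     alternative = "two.sided")$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("permutation test rejects bad input", {
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
  expect_error(permutation_test(1:3, 1:3, n_perm = 0), "n_perm")
})

test_that("two-phase regression recovers an exact piecewise-linear breakpoint
           with zero error", {
  t <- 10:150
  y <- ifelse(t < 100, 0, t - 100)
  fit <- two_phase_regression(t, y, fit_range = c(10, 150))
  expect_equal(fit$r, 100, tolerance = 1e-9)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
  expect_true(fit$valid)
  expect_true(fit$in_range)
})

test_that("two-phase regression flags constant series as invalid (parallel
           lines)", {
  fit <- two_phase_regression(0:200, rep(2.5, 201))
  expect_false(fit$valid)
  expect_true(is.na(fit$r))
  expect_equal(fit$a0, 0)
  expect_equal(fit$a1, 0)
})

test_that("two-phase regression matches an independent exhaustive lm() oracle
           on random series", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    t <- sort(sample(0:200, n))
    y <- cumsum(rnorm(n))
    fit <- two_phase_regression(t, y, fit_range = range(t))
    ora <- oracle_two_phase(t, y, fit_range = range(t))
    expect_equal(fit$sse, ora$sse, tolerance = 1e-8)
    expect_equal(fit$split_index, ora$m)
    expect_equal(fit$a0, ora$a0, tolerance = 1e-8)
    expect_equal(fit$a1, ora$a1, tolerance = 1e-8)
  }
})

test_that("two-phase regression reports out-of-range intersections and
           rejects short inputs", {
  # breakpoint outside the fitted interval: fitted lines intersect left of it
  t <- 10:150
  y <- 0.5 * (t - 5)
  fit <- two_phase_regression(t, y)
  expect_error(two_phase_regression(1:3, 1:3), "4 points")
  expect_error(two_phase_regression(c(1, 1, 2, 3), c(1, 2, 3, 4)),
               "strictly increasing")
})

test_that("moving average is the identity on constants and preserves affine
           ramps away from edges", {
  expect_equal(moving_average(rep(3, 30), 5, 1), rep(3, 30))
  ramp <- seq(0, 29)
  sm <- moving_average(ramp, 5, 1)
  expect_equal(sm[3:28], ramp[3:28])
})

test_that("moving average spreads a unit impulse into 1/w on the centered
           window", {
  y <- rep(0, 41); y[21] <- 1
  w <- 5 # ceiling(5 / 1), already odd
  sm <- moving_average(y, 5, 1)
  expect_equal(sm[19:23], rep(1 / w, w))
  expect_equal(sum(sm > 0), w)
})

test_that("even windows are widened to odd and the output keeps the input
           length and mean on periodic inputs", {
  y <- rep(c(1, 0), 25)
  sm <- moving_average(y, 4, 1) # 4 bins -> forced to 5
  expect_length(sm, length(y))
  expect_equal(mean(sm), mean(y), tolerance = 0.02)
  expect_error(moving_average(1:10, 0.5, 1), "window_ms")
})

test_that("Anscombe transform has the closed form at zero, is monotone, and
           stabilises Poisson variance near one", {
  expect_equal(anscombe(0), 2 * sqrt(0.375))
  x <- 0:100
  expect_true(all(diff(anscombe(x)) > 0))
  set.seed(3)
  v <- var(anscombe(rpois(10000, 30)))
  expect_gt(v, 0.85)
  expect_lt(v, 1.15)
  expect_error(anscombe(-1), "non-negative")
})
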