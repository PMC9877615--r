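#' One-sided (or two-sided) permutation test on a difference of means
#'
#' Nonparametric test of the difference `mean(x) - mean(y)` against a null
#' distribution built by re-shuffling the pooled observations. Used throughout
#' the pipeline instead of parametric tests, because neural consistency and
#' population-consistency values are not Gaussian across neurons.
#'
#' The p-value uses the add-one convention
#' `p = (n_extreme + 1) / (n_perm + 1)`, so it can never be exactly zero and
#' its minimum attainable value is `1 / (n_perm + 1)`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param n_perm Number of shuffles of the pooled data (default 10000).
#' @param alternative `"greater"` tests `mean(x) > mean(y)`, `"less"` the
#'   reverse, `"two.sided"` the absolute difference.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A list of class `"permutation_result"` with elements `observed`,
#'   `p`, `n_perm` and `alternative`.
#' @examples
#' permutation_test(rnorm(20, 1), rnorm(20, 0), n_perm = 999, seed = 1)
#' @export
permutation_test <- function(x, y, n_perm = 10000L,
                             alternative = c("greater", "less", "two.sided"),
                             seed = NULL) {
  alternative <- match.arg(alternative)
  fail_if(list(
    "x must be a non-empty numeric sample" = !(is.numeric(x) && length(x) > 0L),
    "y must be a non-empty numeric sample" = !(is.numeric(y) && length(y) > 0L),
    "n_perm must be >= 1" = !(is.numeric(n_perm) && n_perm >= 1)
  ))
  n_perm <- as.integer(n_perm)
  observed <- mean(x) - mean(y)
  z <- c(x, y)
  if (length(unique(z)) == 1L) {
    warning("all values identical across both samples; p = 1", call. = FALSE)
    return(structure(list(observed = observed, p = 1, n_perm = n_perm,
                          alternative = alternative),
                     class = "permutation_result"))
  }
  nx <- length(x)
  n <- length(z)
  tot <- sum(z)
  stats <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(b) {
      sx <- sum(z[sample.int(n, nx)])
      sx / nx - (tot - sx) / (n - nx)
    }, numeric(1))
  })
  eps <- 1e-12 * max(1, abs(observed))
  n_extreme <- switch(alternative,
    greater   = sum(stats >= observed - eps),
    less      = sum(stats <= observed + eps),
    two.sided = sum(abs(stats) >= abs(observed) - eps)
  )
  structure(list(observed = observed,
                 p = (n_extreme + 1) / (n_perm + 1),
                 n_perm = n_perm,
                 alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed = %.4g, p = %.4g (%d shuffles)\n",
              x$alternative, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Two-phase linear regression
#'
#' Fits a pair of straight lines `y0 = a0 x + b0` (early phase) and
#' `y1 = a1 x + b1` (late phase) to a time series by exhaustively scanning all
#' candidate partition points of the grid (each interior grid point with at
#' least two points on each side), fitting each side by ordinary least squares
#' and keeping the partition that minimises the total sum of squared
#' deviations. The intersection of the two lines,
#' `r = (b1 - b0) / (a1 - a0)`, estimates the time at which the series changes
#' regime; in this package it is the modulation-latency estimator for
#' figure-ground dependent firing.
#'
#' `r` is the line intersection, not the best partition point: the two can
#' differ, and `r` may fall outside `fit_range` (reported with `in_range =
#' FALSE`). When the optimal lines are parallel within a slope tolerance of
#' `1e-12` (per-unit-time series units), the fit is flagged `valid = FALSE`
#' and `r` is `NA`.
#'
#' @param t Time grid in ms, strictly increasing.
#' @param y Series values at `t`.
#' @param fit_range Closed interval in ms restricting the points used
#'   (default `c(10, 150)`).
#' @return A list of class `"two_phase_fit"` with `a0, b0, a1, b1, r, sse,
#'   valid, in_range, split_index` (index, within the fitted points, of the
#'   last point of the early phase).
#' @export
two_phase_regression <- function(t, y, fit_range = c(10, 150)) {
  fail_if(list(
    "t and y must have equal length" = length(t) != length(y),
    "t must be strictly increasing" = any(diff(t) <= 0),
    "fit_range must be an interval" = !(length(fit_range) == 2 &&
                                          fit_range[1] < fit_range[2])
  ))
  keep <- t >= fit_range[1] & t <= fit_range[2]
  tt <- t[keep]; yy <- y[keep]
  n <- length(tt)
  if (n < 4L) stop("need at least 4 points inside fit_range", call. = FALSE)

  # Prefix sums give closed-form OLS and SSE for every contiguous segment.
  cs_t  <- cumsum(tt);  cs_y  <- cumsum(yy)
  cs_tt <- cumsum(tt^2); cs_ty <- cumsum(tt * yy); cs_yy <- cumsum(yy^2)
  seg <- function(i, j) { # OLS fit of points i..j
    m <- j - i + 1
    st <- cs_t[j] - if (i > 1) cs_t[i - 1] else 0
    sy <- cs_y[j] - if (i > 1) cs_y[i - 1] else 0
    stt <- cs_tt[j] - if (i > 1) cs_tt[i - 1] else 0
    sty <- cs_ty[j] - if (i > 1) cs_ty[i - 1] else 0
    syy <- cs_yy[j] - if (i > 1) cs_yy[i - 1] else 0
    sxx <- stt - st^2 / m
    sxy <- sty - st * sy / m
    a <- sxy / sxx
    b <- (sy - a * st) / m
    sse <- max(0, (syy - sy^2 / m) - a * sxy)
    c(a = a, b = b, sse = sse)
  }
  splits <- 2:(n - 2)
  best <- NULL; best_sse <- Inf; best_m <- NA_integer_
  for (m in splits) {
    L <- seg(1L, m); R <- seg(m + 1L, n)
    tot <- L[["sse"]] + R[["sse"]]
    if (tot < best_sse - 1e-15) {
      best_sse <- tot; best <- list(L = L, R = R); best_m <- m
    }
  }
  a0 <- best$L[["a"]]; b0 <- best$L[["b"]]
  a1 <- best$R[["a"]]; b1 <- best$R[["b"]]
  valid <- is.finite(a0) && is.finite(a1) && abs(a1 - a0) > 1e-12
  # solving a0 r + b0 = a1 r + b1 for the intersection time
  r <- if (valid) (b0 - b1) / (a1 - a0) else NA_real_
  structure(list(a0 = a0, b0 = b0, a1 = a1, b1 = b1, r = r,
                 sse = best_sse, valid = valid,
                 in_range = valid && r >= fit_range[1] && r <= fit_range[2],
                 split_index = best_m),
            class = "two_phase_fit")
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat(sprintf(
    "Two-phase fit: r = %.2f ms (valid = %s, in_range = %s), sse = %.4g\n",
    x$r, x$valid, x$in_range, x$sse))
  cat(sprintf("  early: y = %.4g t + %.4g | late: y = %.4g t + %.4g\n",
              x$a0, x$b0, x$a1, x$b1))
  invisible(x)
}

#' Centered moving average with shrinking edges
#'
#' Boxcar smoother used on differential PSTHs before latency estimation. The
#' window covers `ceiling(window_ms / bin_ms)` bins, forced odd by adding one
#' bin when even, and is centered on each output bin; at the series edges the
#' window shrinks to the available bins, so the output has the same length as
#' the input.
#'
#' @param y Numeric series.
#' @param window_ms Averaging window width in ms (default 50).
#' @param bin_ms Width of one bin in ms (default 1).
#' @return Smoothed series, `length(y)` long.
#' @export
moving_average <- function(y, window_ms = 50, bin_ms = 1) {
  fail_if(list(
    "window_ms must be >= bin_ms" = window_ms < bin_ms,
    "bin_ms must be positive" = bin_ms <= 0,
    "y must be numeric" = !is.numeric(y)
  ))
  w <- ceiling(window_ms / bin_ms)
  if (w %% 2 == 0) w <- w + 1L
  n <- length(y)
  if (n <= w) stop("series must be longer than the smoothing window",
                   call. = FALSE)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Anscombe transform of spike counts
#'
#' `2 * sqrt(x + 3/8)`: a variance-stabilising map that takes Poisson counts
#' to an approximately Gaussian variable with unit variance, used to check
#' that the figure-ground ANOVA screening does not depend on the Poisson
#' nature of spike counts.
#'
#' @param x Non-negative spike counts.
#' @return Transformed values; strictly increasing in `x`.
#' @export
anscombe <- function(x) {
  fail_if(list(
    "x must be numeric" = !is.numeric(x),
    "x must be non-negative" = any(x < 0, na.rm = TRUE)
  ))
  2 * sqrt(x + 0.375)
}
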