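#' @importFrom stats aggregate anova coef cor cor.test ks.test lm oneway.test
#'   pnorm predict quantile rbeta rbinom residuals rlnorm rnorm rpois runif
#'   sd t.test var
#' @importFrom utils head tail
#' @importFrom rlang .data
NULL

.datatable.aware <- TRUE

# Evaluate `code` under a fixed RNG state when `seed` is non-NULL, leaving the
# caller's RNG untouched. NULL seed means "use the ambient RNG stream".
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds from one master seed
#' through this map, so that a single integer reproduces a whole run while
#' stages remain decoupled (changing the number of permutations in one stage
#' does not shift the random stream of another).
#'
#' @param seed Master seed (integer).
#' @param tag Character tag naming the stage (e.g. `"pnc"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483646 + 1)
}

# Input check helper: stop with a labelled message listing all violations.
fail_if <- function(violations) {
  bad <- vapply(violations, isTRUE, logical(1))
  if (any(bad)) {
    stop(paste(names(violations)[bad], collapse = "; "), call. = FALSE)
  }
  invisible(NULL)
}

# Half-open window count: number of values in [from, to).
count_in_window <- function(t, from, to) sum(t >= from & t < to)
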