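Package: fgcons
Title: Figure-Ground Perceptual and Neural Consistency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the perceptual consistency of figure-ground judgements on
    local natural image patches to the reliability, magnitude and latency of
    figure-ground dependent modulation in V4 spiking activity. Implements the
    perceptual-consistency statistic from two-alternative forced-choice trial
    tables, receptive-field based figure/ground labelling and neuron screening,
    single-cell neural consistency via accuracy-maximising spike-count
    thresholds, population decoding of pooled spike counts with cross-validated
    kernel classifiers, differential-response magnitudes, modulation-latency
    estimation by two-phase linear regression, one-sided permutation tests,
    and an inhomogeneous-Poisson generator that produces psychophysics and
    spike data from a shared latent ambiguity for ground-truth recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    withr,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
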