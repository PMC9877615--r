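# fgcons

Links human figure-ground perception to the reliability, magnitude and
timing of figure-ground modulation in V4 spiking activity — as a tested,
reusable analysis pipeline, exercised end to end on synthetic psychophysics
and spike data with known ground truth.

## The problem

A small crop of a natural scene contains an object contour; observers judge
which side is the object (figure). Some patches are judged identically by
everyone on every trial, others are ambiguous. V4 neurons fire differently
depending on whether figure or ground covers their receptive field. Does the
consistency of human figure-ground judgement, stimulus by stimulus, track
the consistency, magnitude and latency of that neural modulation? The
package implements every statistic this question needs, for anyone with
forced-choice trial tables and spike-event tables:

* **Perceptual consistency** per stimulus from two-alternative forced
  choices, `PC_i = (1/N_s) Σ_j max(a_ij, b_ij)/N_v × 100` (50 % = chance),
  mean reaction times, and EASY/HARD stimulus groups (top/bottom k by PC).
* **Neuron screening**: isotropic 2-D Gaussian receptive-field fits to
  grating-grid maps; veridical F/G/non-FG labels per (neuron, patch) from
  the fitted center and the psychophysically determined figure side;
  responsiveness t-tests and figure-ground ANOVAs (pooled and
  original-mirror paired), with the Anscombe transform `2√(x + 3/8)` as a
  distributional check.
* **Neural consistency (NC)**: the correct rate of figure-ground
  determination from single-neuron spike counts under an exhaustively
  accuracy-maximised threshold, pooled over 400 trials per stimulus group.
* **Population-based neural consistency (PNC)**: cross-validated RBF-SVM
  accuracy on label-aligned pooled populations of 1-40 neurons
  (80 patches x p neurons, stratified 5-fold, 200 repeats).
* **Modulation magnitude** `ΔR = R_pref − R_non.pref` on original-mirror
  pairs and its rank correlation with PC.
* **Modulation latency**: two-phase linear regression (intersection of two
  least-squares lines) on the 50-ms-smoothed differential population PSTH
  over 10-150 ms.
* **Permutation tests** (one-sided, add-one convention) for every group
  comparison, and a **synthetic-data generator** in which observers and
  Poisson-spiking neurons share one latent per-stimulus ambiguity, so every
  stage has ground truth to recover.

## Worked example

The `analysis/` directory is the study as a numbered workflow; each script
reads the previous stage's outputs from `results/`:

```sh
Rscript analysis/01_simulate.R       # default world, seed 1
Rscript analysis/02_psychophysics.R
Rscript analysis/03_screening.R
Rscript analysis/04_single_cell.R
Rscript analysis/05_population.R
Rscript analysis/06_dynamics.R
```

With the default configuration (105 stimuli x 10 observers x 8 variants;
100 neurons, half of them built figure-ground modulated, x 210 patches x 10
repeats; seed 1) the stages print:

```
PC across 105 stimuli: mean 74.3%, SD 7.5% (Gaussian KS p = 0.083)
PC vs z-scored RT: Pearson r = -0.80, slope = -0.1055 per PC point
100/100 neurons responsive; 46 (46%) figure-ground modulated, 89% of them figure-preferring
neural consistency over 46 neurons: EASY 55.3% (SD 2.0), HARD 53.7% (SD 1.4)
one-sided paired permutation p = 0.0002; 73.9% of neurons higher with EASY
EASY-HARD gap grows from 8.1 points at p = 1 to 21.3 at p = 40
PC vs delta-R over 46 neurons: mean Spearman rho 0.121, one-sided t(45) = 7.45
modulation latency, EASY group: 51.6 ms
modulation latency, HARD group: 113.5 ms
```

Reading this: the perceptual-consistency distribution is approximately
Gaussian in the low-70s with an ~8-point spread; consistently judged
stimuli are answered faster (negative PC-RT correlation); screening
recovers close to the built 50 % modulated fraction (the ANOVA's ~5 %
false-positive rate and ~93 % sensitivity roughly offset) and the built
83 % figure-preference mix; single-neuron consistency is only a few points
above chance but reliably higher for EASY stimuli; pooling neurons widens
the EASY-HARD decoding gap as the population grows; per-neuron modulation
magnitude rank-correlates positively with PC; and figure-ground modulation
emerges ~60 ms earlier for consistently perceived stimuli. These are the
five qualitative effects the generator builds in through its shared latent
ambiguity, recovered by the full pipeline.

`run_report()` performs the same pipeline in one call and writes a stamped
output bundle (tables, `headline.json`, exclusion log, resolved
configuration) given the four input tables — simulated or real.

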