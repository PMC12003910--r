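---
title: "Models and methods behind luckydoor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind luckydoor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luckydoor)
```

This vignette explains the scientific model the package implements, the
choices we made where the design was genuinely open, and what the
synthetic generators do and do not emulate. Everything quantitative
stated here is computed by the package's test suite or acceptance script;
nothing is quoted from external data.

## The task model

The Lucky Door task is a two-armed bandit. Each door is a Bernoulli deck:
with probability `p_gain` it pays `gain` coins, otherwise `loss` coins.
The experimental block opposes RareG (0.3 / +60 / −20) to RareL
(0.7 / +20 / −60); the baseline block uses 0.3 / +70 / −30 and
0.7 / +30 / −70, equating EV at zero.

**EV horizon.** The per-trial expectations of the experimental decks are
+4 and −4 coins. The task's display and conventional labels report EV
accumulated over ten trials (+40 / −40 / 0), so `deck_ev()` defaults to a
10-trial horizon with `horizon` an explicit argument. This is a reporting
convention, not a model assumption: all invariants (antisymmetry in the
experimental block, zero baseline EV) hold at every horizon.

**Outcome sampling** is i.i.d. Bernoulli per trial. A pre-generated
fixed-ratio schedule is a plausible alternative implementation of the
same marginal payoff structure; we default to i.i.d. draws because
nothing in the design constrains the schedule, and the Win-Stay statistic
conditions only on realized wins. Block order is counterbalanced by
subject-index parity.

## Synthetic cohort

The covariate generator draws per-group demographics and mental-health
scores truncated to instrument ranges (GAD7 0–21, PHQ9 0–27, family
affluence 0–9). Default group directions follow the design the package
serves — elevated anxiety, depression and recent-trauma endorsement in
exposed groups, age- and gender-matched, with ethnicity mix differing
between sites — but the magnitudes are configuration, and
`null_covariate_config()` gives exchangeable groups for calibration work.

Behavior comes from explicit agents, because the analysis needs choice
sequences whose Win-Stay has known ground truth:

* **WSLS agent** — after a RareG win, stay with probability
  `p_stay_win_rareG`; after any loss, switch with probability
  `p_shift_loss`; after a RareL win, stay with probability
  `p_stay_win_rarel` (default 0.5, i.e. indifferent — the task design
  places no constraint on this transition, and Win-Stay on RareG is
  insensitive to it). The empirical Win-Stay of this agent is an unbiased
  estimator of `p_stay_win_rareG`, which the suite verifies by
  simulation.
* **Delta-rule agent** — per-door value update `V <- V + alpha (r − V)`
  with softmax choice and multiplicative loss aversion; provided as a
  learning benchmark (it comes to prefer the higher-EV door).

The cohort generator draws each subject's experimental-block stay
probability from their group distribution (defaults 0.45 for directly
exposed vs 0.65 otherwise, between-subject SD 0.1 — a deficit of two
subject-level SDs, the medium-to-large regime the design is powered for)
and the baseline-block stay probability from a single common distribution,
so no group effect exists at baseline by construction.

## Behavioral statistics and models

`win_stay()` implements the ratio of stays after RareG wins. Two edge
cases are under-determined by the verbal definition and fixed here: a win
on the final trial has no follow-up and is excluded from the denominator,
and a subject with no qualifying wins has an undefined (NA) statistic and
is dropped from models with a logged message — never imputed as zero,
which would conflate "never won" with "always shifted".

`gain_frequency_bias()` is defined as the proportion of baseline-block
trials on which RareL was chosen. The metric's name admits several
formalizations; we chose the choice proportion because the baseline block
equates EV, so any preference for RareL there is exactly a preference for
frequent small gains.

`fit_group_model()` is iteratively-reweighted least squares with bisquare
weights and tuning constant 4.685 (95% Gaussian efficiency, the
conventional default of the robust option in mainstream linear-model
toolboxes), on a z-scored outcome and z-scored continuous covariates with
reference coding (reference group: non-exposed). Term p-values use the t
distribution with residual degrees of freedom; model-level adjusted R²,
F and p are computed from the final robust weights. A perfectly
collinear design raises an error naming the offending columns rather than
silently dropping them. A perfect (zero-residual) fit is handled by the
IRLS machinery itself, which converges to the least-squares solution.

## Synthetic EEG

Each epoch is the sum of:

* **1/f background** — Gaussian noise spectrally shaped to `1/f^γ`
  (γ = 1, overall SD 10 µV), the canonical broadband EEG spectrum. The
  suite checks the fitted log–log slope over 2–40 Hz.
* **Parietal alpha burst** — a 10 Hz carrier under a raised-cosine
  plateau envelope spanning 0–1500 ms, weight 1 on Pz/P3/P4/POz and 0.4
  on their montage neighbors (volume-conduction-like smearing), with a
  *phase consistent across trials* so the signal survives trial
  averaging. The subject's amplitude is drawn from their group
  distribution: 5.5 µV (directly exposed) vs 4 µV (others), SD 2 µV,
  i.e. a configured standardized difference of d = 0.75 — the
  medium-to-large parietal alpha effect the pipeline is designed to
  detect.
* **Artifacts** — frontal-dominant Gaussian blink transients (110–160 µV,
  5% of trials) and in-band 5 Hz transients of 130–170 µV peak (2% of
  trials; kept within the 1–45 Hz pass-band so the amplitude violation
  survives broadband filtering), both flagged in `trial_info` so
  rejection sensitivity is measurable.

The default montage is a 24-channel 10–20 subset with 2-D layout
coordinates; adjacency is distance-based (radius 0.65 layout units, which
yields a connected graph). The montage is data, not a constant — any
layout containing the four parietal channels works.

What the generator does **not** emulate: realistic source mixing through
a head model, induced (non-phase-locked) oscillatory dynamics, heavy-tailed
artifact families (EMG, electrode pops), channel dropout, or any coupling
between behavior and neural amplitude (none is injected by default, so
interaction models are null-calibrated out of the box). Passing tests
therefore demonstrate correctness and calibration of the *statistics*,
not realism of the signals.

## Preprocessing chain

* **Filtering** is windowed-sinc FIR (Hamming), transition bandwidth
  `min(max(0.25·edge, 2 Hz), room)` at each band edge and length
  `3.3 · fs / min(transition)` taps. Because the kernel is symmetric, one
  FFT convolution with group-delay compensation is exactly zero-phase
  (verified: burst peak latency preserved to the sample). Edges are
  handled by odd reflection padding of one kernel length. The broadband
  filter (1–45 Hz at 250 Hz) passes 10 Hz within 5% and attenuates
  0.2 Hz drift by more than 20 dB.
* **Trial rejection** applies the 100 µV absolute-amplitude rule first,
  then the iterative rule: per-trial deviation summary (default: maximum
  absolute amplitude; variance available), drop trials >5 SD from the
  remaining distribution, recompute, at most 8 passes. The log accounts
  for every dropped trial exactly once.
* **Band activity** is evoked: band-filtered trials are averaged, giving
  the phase-locked waveform in µV. Baseline correction subtracts the
  per-channel mean over −250 to −50 ms.
* **Period summaries.** The signed time-mean of a narrowband oscillation
  over a 500-ms window is approximately zero regardless of its amplitude
  (exactly zero for the five full cycles of 10 Hz), so a signed mean
  cannot carry an alpha-amplitude effect between groups. The default
  summary is therefore the mean **Hilbert envelope of the evoked
  waveform** over the period, referenced to the mean envelope over the
  baseline window — a µV magnitude that preserves trial-averaging's noise
  suppression while measuring oscillatory amplitude. The signed mean
  remains available (`summary = "mean"`) for deflection-like signals.
* **Cross-subject masking** replaces values >5 SD from the cross-subject
  mean with NaN per channel × period × band; downstream statistics
  exclude NaN per electrode.

Periods are half-open intervals (`[0,500)`, `[500,1000)`,
`[1000,1500)` ms) so they tile the post-choice window without overlap;
the baseline window is closed.

## Group statistics

The cluster permutation test uses per-electrode pooled-variance t
statistics, a two-sided cluster-forming threshold of p < 0.05, same-sign
adjacency clustering, cluster mass = Σ|t|, and a max-cluster-mass null
over label permutations (default 10,000), giving family-wise control
across electrodes. The cluster-forming threshold and mass statistic are
conventional choices; the test marks electrodes at a strict display
threshold (default p < 1e−4, the smallest attainable level with 10,000
permutations is 1/10001) and flags significance at 0.05, both
configurable. Each map's p-value for the 9-map FDR family is its smallest
cluster p (1 when no cluster forms); Benjamini–Hochberg is the FDR
procedure throughout.

Parietal cluster comparisons are pooled-variance t-tests with
Cohen's d = Δmean / pooled SD; pooled rather than Welch, consistent with
reporting full-sample degrees of freedom after listwise NaN exclusion.
The neurobehavioral models are robust fits of
`WinStay ~ group * alpha + age + ethnicity + GAD7` — the covariates that
differ between the contrast sides — per electrode (cluster mean plus
Pz/P3/P4/POz) and period, with BH correction across the 12
electrode × period models. Within-group Spearman correlations follow up
interactions; a constant input yields an explicitly undefined rho.

Demographic comparisons use rank-sum tests for ordinal/continuous
variables and uncorrected chi-square tests on contingency tables for
gender and ethnicity, with `**`/`***` star coding at 0.01/0.001.

## Reproducibility and problem sizes

One master seed expands to fixed per-stage child seeds
(`seed + 104729·k mod 2³¹−1`), so stages can be re-run in isolation and a
re-run of the full pipeline is checksum-identical file by file. The
suite's simulation studies use sizes chosen to make Monte-Carlo error
small relative to the tolerances they check: 200 cohort replicates for
behavioral power and type-I rate (3-SE binomial bands), 200 replicates ×
1,000 permutations for family-wise error calibration, 100 replicates for
parietal-effect sensitivity, and one study-scale pipeline run (cohort
27/21/27, EEG loss 8/7/3, so 57 EEG subjects) for effect-size recovery,
judged against the analytic 95% sampling interval of Cohen's d at
n = 28/28.

## Known limitations

* Artifact handling is rule-based (amplitude and deviation criteria);
  source-decomposition cleaning of ocular/myogenic components is out of
  scope, so residual structured artifacts below 100 µV would survive in
  real data.
* No source localization: all statistics are channel-space.
* Epoch serialization uses a versioned RDS payload plus tidy CSV; there
  is no HDF5/EDF interchange in this build.
* The agents are deliberately minimal generative stand-ins; they are not
  fitted cognitive models and make no claims about participant learning
  dynamics.
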