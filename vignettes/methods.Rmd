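---
title: "Joint feature-subset and network-size optimization for P300 classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint feature-subset and network-size optimization for P300 classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300elm)
```

## The problem

In a guilty-knowledge test, a probe stimulus that the subject recognizes
elicits a P300 — a positive event-related deflection at centro-parietal
electrodes roughly 300–400 ms after stimulus onset. Probe responses from
knowledgeable ("guilty") subjects therefore carry a P300 (class +1), while
probe responses from naive ("innocent") subjects do not (class −1).
`p300elm` classifies averaged probe responses between these two classes and,
more importantly, optimizes the *structure* of the classifier: which
features it sees and how many hidden nodes it has.

The classifier is an extreme learning machine (ELM): a single-hidden-layer
feed-forward network whose input weights $w_i$ and biases $b_i$ are drawn
randomly (uniform on $[-1, 1]$) and never adjusted. Writing
$H_{ji} = g(w_i \cdot x_j + b_i)$ with the sigmoid
$g(z) = 1/(1+e^{-z})$, training reduces to the linear least-squares problem
$\min_\beta \lVert H\beta - T \rVert$, solved by the Moore–Penrose
pseudoinverse $\beta = H^{+}T$ — the minimizer with the smallest Euclidean
norm, which is also the choice associated with better generalization.
Because training is a single linear solve, an exhaustive grid search over
the classifier's two structural parameters is affordable.

## Pipeline and assumptions

1. **Epochs** run from 0.2 s before to 0.8 s after stimulus onset at
   500 Hz — 500 samples, with sample $i$ at time $t_0 + i/f_s$ (half-open
   epoch, so 1 s × 500 Hz is exactly 500 samples).
2. **Baseline correction** subtracts the mean of the pre-stimulus samples
   from the whole epoch (idempotent; requires $t_0 < 0$).
3. **Averaging** pools consecutive, non-overlapping groups of 5 same-subject
   trials; the remainder that does not fill a group is dropped
   ($\lfloor n/5 \rfloor$ averages). Grouping follows trial order; the
   procedure assumes trials of one subject share one class label.
4. **Features** (31 per response, fixed order):
   - *Time domain*, computed on the post-stimulus window $t \ge 0$:
     $V_{max}$ (µV), $t_{max}$ (s, from stimulus onset), $R_{L/A} =
     t_{max}/V_{max}$ (s/µV; 0 by convention when $V_{max}=0$), $V_{min}$,
     $V_{ptp} = V_{max}-V_{min}$, and the positive area
     $A_p = \sum \max(x, 0)/f_s$ (µV·s, rectangle rule).
   - *Frequency domain*, from a Burg autoregressive spectrum of the full
     epoch (order 20, 512 frequency bins on $[0, f_s/2]$): $f_{max}$,
     the power-weighted mean frequency $f_{mean}$, and $A_{lf}$, the
     rectangle-rule power in the 0.1–3.9 Hz band containing the P300.
   - *Time–frequency*: the 22 level-6 approximation coefficients of a
     discrete wavelet decomposition, covering $[0, (f_s/2)/2^6] =
     [0, 3.90625]$ Hz.
5. **Normalization** maps each feature linearly so the *training* minimum
   and maximum land at −1 and +1; constant features map to 0, unseen values
   are not clipped.

## The joint grid search

Features are ranked once per cross-validation fold by descending F-score

$$F_i \;=\; \frac{(\bar{x}_i^{+}-\bar{x}_i)^2 + (\bar{x}_i^{-}-\bar{x}_i)^2}
{s_{i,+}^{2} + s_{i,-}^{2}},$$

with sample variances ($1/(n-1)$). The search sweeps the subset size
$S = 1 \ldots 31$, adding features in rank order, crossed with the
hidden-node count $K = S \ldots S+20$ (the span of 21 candidates keeps the
network within a practical size while letting it grow with the input
dimension). Every cell is scored by balanced training accuracy under
subject-wise cross-validation: each outer fold holds out one subject per
class (14 folds at the study's 14 + 14 design), and an inner stratified
10-fold loop on the fold's training responses produces the fold's
sensitivity and specificity; `BA_train` averages these over folds. Finally,
one ELM per fold is retrained at the selected $(S^*, K^*)$ on the fold's
full training set and evaluated on the held-out pair, giving `TE_sen`,
`TE_spe` and `BA_test`.

### Design choices that were genuinely open

- **Selection rule.** The literal rule "take the `BA_train` maximizer"
  often lands on a large network whose accuracy exceeds much smaller cells
  by a hair. We select the cell with the smallest $S$, then smallest $K$,
  whose `BA_train` is within `parsimony` (default 0.5 percentage points,
  configurable; 0 restores the strict maximizer) of the grid maximum —
  an accuracy that approximates the best value with a markedly more compact
  network is regarded as the better optimum.
- **Where ranking and normalization are fit.** Strictly inside each outer
  fold, on training subjects only. Fitting them once globally is a common
  but leaky shortcut; it is available for comparison via
  `rank_scope = "global"`. The no-leakage property is tested by poisoning
  held-out rows and asserting the fold's trained model is bit-identical.
- **Inner/outer aggregation.** The per-cell accuracy of a fold is the mean
  over the 10 inner folds; `BA_train` then averages fold sensitivities and
  specificities across outer folds. The inner split is fixed per outer fold
  (seeded), shared by all grid cells, so cells differ only in their
  features and hidden layers.
- **Seeding.** One master seed fans out deterministically (an LCG-style
  mixer on 32-bit-safe integers) to the simulator, the inner splits, one
  weight draw per (fold, S, K) cell, and one per final fold model. The
  whole search is bit-reproducible, and no two cells share correlated
  draws.
- **Wavelet family and boundary mode.** Only the coefficient count (22) and
  the band label (0.1–3.9 Hz) constrain the choice. A length-16 orthogonal
  Daubechies filter (8 vanishing moments) with zero-padding full
  convolution is the standard combination for which the cascade
  $n_j = \lfloor (n_{j-1}+15)/2 \rfloor$ maps 500 samples to exactly 22
  level-6 approximation coefficients; both are exposed as arguments.
- **Analysis windows.** Time-domain features use the post-stimulus window
  only; the spectral and wavelet features use the full 1 s epoch, and
  $t_{max}$ is measured from stimulus onset (latencies then land near
  350 ms, the conventional reporting scale).
- **PCA comparator.** `selector = "pca"` replaces the top-$S$ subset by the
  first $S$ principal components (eigendecomposition of the covariance of
  the mean-centered, normalized training rows; eigenvector signs fixed by
  making the largest-magnitude entry positive). Centering is applied before
  projection since the covariance being decomposed is central.

## Numerical choices

- Pseudoinverse cutoff: singular values below $10^{-10}\sigma_{max}$ are
  treated as zero.
- For speed, the solver first attempts a Cholesky solve of the normal
  equations when $H$ has more rows than columns; the singular values of the
  $K \times K$ Cholesky factor equal those of $H$, so the solver falls back
  to the SVD pseudoinverse whenever the exact condition number exceeds
  $10^3$ (or the factorization fails). In the well-conditioned regime both
  routes agree to $10^{-14}$.
- Degenerate conventions, all tested: $F = 0$ for $0/0$ and $+\infty$ for a
  separated but spread-free feature (ranked first; ties broken by original
  column order, stable); $R_{L/A} = 0$ when $V_{max} = 0$; an all-constant
  signal has an all-zero Burg spectrum; an all-zero spectrum yields
  $(f_{max}, f_{mean}, A_{lf}) = (0,0,0)$; a zero ELM score classifies as
  +1; a paired t-test on zero-variance differences warns and returns an
  undefined p value.
- The Burg stage removes the signal mean before fitting (standard spectral
  practice; baseline correction has already removed most of it).

## What the simulator emulates — and what it does not

`simulate_epochs()` emulates the study conditions: 14 subjects per class,
1 s epochs at 500 Hz, and a monophasic P300 modeled as a raised-cosine bump
(default peak 8 µV ± 2 between trials, ± 2 between subjects; latency
350 ± 30 ms; width 300 ms) added to Gaussian background noise (default SD
5 µV per single trial, white by default with an AR(1) option for the
low-pass character of bandpassed EEG). With the default 105 trials per
subject and 5-trial averaging, each subject contributes 21 averaged
responses — 294 per class, matching the roughly 300 per group of the
original design. The defaults place the classes in the high-separability
regime (test balanced accuracies near 99%) that averaged probe recordings
exhibit.

It does **not** emulate target/irrelevant stimulus channels, multiple
electrodes, ocular artifacts, non-stationary or stimulus-locked noise, or
behavioral (button-press) errors. Passing tests on simulated data therefore
demonstrate the correctness and leak-freedom of the pipeline, not field
performance on real EEG: real recordings have colored, non-Gaussian,
partially time-locked noise and inter-session variability that the
generator deliberately omits. `simulate_feature_table()` bypasses the
waveform stage entirely and plants a known number of informative feature
columns (class separation 3 within-class SDs, per-subject offsets of SD
0.5), which is the ground truth used for structure-recovery checks.

One calibration subtlety: the generator's amplitude check (class-mean
difference at the latency mean equals the configured amplitude within
Monte-Carlo error) holds with latency jitter disabled; jitter shifts each
trial's peak off the latency-mean sample and biases the sample mean low by
about 8% at the default 30 ms jitter, which is expected behavior, not a
calibration error.

## Problem sizes used by the test suite

The suite exercises the full grid geometry (31 × 21 cells) but at reduced
data scales chosen to keep runs comfortable on one CPU: most unit fixtures
use 4 subjects per class with 20 trials each; the structure-recovery checks
use 10 + 10 subjects with 200 planted-feature responses per class over 5
seeds (about 15 s per search); statistical checks of the simulator use 500
or 2000 single trials. A full-scale run (14 + 14 subjects, 294 averaged
responses per class) completes in a few minutes via `run_pipeline()`.

## Known limitations

- Subject-wise folds require equal subject counts per class; unbalanced
  designs are rejected rather than paired arbitrarily.
- Sensitivity/specificity are per-response, not per-subject; no individual
  diagnostic threshold is implemented (per-subject accuracies are exposed
  in the per-fold test table).
- Comparator classifiers (back-propagation networks, SVMs) are out of
  scope; `paired_ttest()` accepts their per-fold accuracies from external
  runs.
- The F-score, being univariate, cannot credit features that are only
  jointly informative; this is a property of the method, inherited
  deliberately.
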