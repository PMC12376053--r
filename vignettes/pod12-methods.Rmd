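---
title: "Methods: POD12 risk scoring and chaotic forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: POD12 risk scoring and chaotic forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pod12risk)
```

## The problem

Progression of disease within 12 months of diagnosis (POD12) identifies the
diffuse large B-cell lymphoma (DLBCL) patients with the worst outlook: they
respond poorly to salvage therapy, so recognizing them *before* first-line
treatment matters. `pod12risk` implements two complementary halves of a
POD12 analysis:

1. **Cohort half** — a bedside points score built from six dichotomized
   risk factors, with the full diagnostic arithmetic used to validate it.
2. **Forecasting half** — the six factors monitored over time are treated
   as a chaotic multivariate series; phase-space reconstruction feeds a
   CNN-LSTM one-step predictor, and a PSO-tuned general regression neural
   network maps (current or predicted) variable states to a comprehensive
   risk level.

Patient-level data of this kind are private, so the package ships synthetic
generators that reproduce the *statistical structure* the analysis assumes.
Every empirical statement in this vignette is one the test suite or
`scripts/acceptance.R` computes.

## The clinical score (model A) and its validation

Six binary factors enter the score: elevated lactate dehydrogenase
(LDH >= 250 IU/L), elevated beta2-microglobulin (>= 3 umol/L), Ann Arbor
stage III-IV, ECOG performance status >= 2, neutrophil-lymphocyte ratio
NLR >= 1.73, and systemic immune-inflammation index SII >= 304.2.
Beta2-microglobulin carries 2 points (it has by far the largest
multivariable coefficient); the other five carry 1 point each, so scores
range 0-7 and `score >= 4` flags the high-risk group. Model B uses only the
two independent risk factors (ECOG, beta2-MG): both present = high, one =
medium, neither = low. The NCCN-IPI (0-8 points, published scheme) is the
comparator, dichotomized at `>= 4`.

Validation runs through a 2x2 table of high-risk flag against observed
POD12: sensitivity, specificity, PPV, NPV, accuracy
(`(TP + TN) / total`), the positive likelihood ratio, and the
cross-product odds ratio with its Wald interval
`exp(log OR +/- 1.96 * sqrt(1/TP + 1/FP + 1/FN + 1/TN))`. Zero cells mark
the OR undefined rather than applying a continuity correction — the
published tables contain no zero-cell ORs, so nothing is silently shifted.
Cut-offs for the continuous inflammation indices are selected by Youden's
J = sensitivity + specificity - 1, scanning midpoints between distinct
sorted values with `value >= cutoff` coded positive (matching the `>=`
convention of the factor definitions) and ties broken toward the smaller
threshold. A single-proportion power check (normal approximation, no
continuity correction) is included; its null proportion is a *required*
argument because no published value exists — 0.26 happens to reproduce the
printed power 0.927878, but that is reverse-engineering, not ground truth.

## The synthetic cohort: what it emulates

`default_cohort_spec()` encodes the study conditions:

* **Prevalences.** LDH 47.6%, beta2-MG 49.2%, stage III-IV 71.4%,
  ECOG >= 2 46%, rituximab-containing first-line therapy 84.1% — the
  published cohort margins. NLR and SII prevalences are not printed
  anywhere, so they are derived from the printed (sensitivity,
  specificity) pairs at 46% incidence:
  `P(flag) = sens * 0.46 + (1 - spec) * 0.54`, giving 30.2% and 27.0%.
* **Effect structure.** The generating log-odds are the multivariable
  estimates (0.251, 2.615, 0.991, 2.299, 0.408, 1.371); the treatment flag
  is carried with a null coefficient for adjustment only.
* **Intercept.** Calibrated so the *expected* incidence is exactly 46%,
  by enumerating all 2^6 factor combinations (exact, no Monte Carlo) and
  bisecting.
* **Continuous labs.** For factors with a known cut-off, a log-normal lab
  value is generated whose exceedance probability over the cut-off equals
  the flag prevalence, and the flag is re-derived from the lab — so
  cut-off selection can be exercised end to end on consistent data.
* **Independence.** Covariates are generated independently (no published
  correlation structure exists); an exchangeable Gaussian-copula knob is
  available but off by default.

What passing tests on this cohort do **not** show: real covariate
correlation, confounding between labs and treatment, or any non-logistic
outcome mechanism. The generator is a calibration target, not a claim of
clinical realism.

Coefficient recovery is asserted in calibrated form: across 20 seeds at
n = 2000, at least 90% of factors must land within 2 standard errors of
their generating values. A single-seed "all six within 2 SE" check would
fail ~25% of the time for a *perfectly calibrated* estimator (0.95^6), so
per-seed assertions use a 3.5 SE gross-error bound instead.

## Monitoring series and pretreatment

`simulate_series()` provides Lorenz (sigma 10, rho 28, beta 8/3, dt 0.01),
Mackey-Glass (delay 17), the logistic map (r = 3.9), a sinusoid, and a
constant control. Two generator conditions are deliberate:

* The sinusoid has a **positive baseline** (offset 2, amplitude 1):
  clinical labs are positive quantities, and MAPE is unstable around zero
  targets.
* Its period (41.3 samples) is **incommensurate with the sampling grid**.
  An integer period makes every sampled value recur exactly, which
  degenerates histogram mutual information (flat plateau) and
  false-nearest-neighbour statistics (the nearest neighbour is always an
  exact same-phase duplicate). Real monitoring schedules never align
  exactly with a physiological cycle.

Missingness is missing-completely-at-random. Pretreatment fills interior
gaps with the before/after mean `x_i = (x_{i-1} + x_{i+1}) / 2`, iterated
to its fixed point for consecutive gaps (the fixed point is the linear
interpolant between the observed endpoints); boundary gaps take the
nearest observed value and are logged. The control parameter mu = 0.85
then damps *imputed* entries (`x <- mu * x`). Reading the correction as
applying to the filled values only is the natural reading of the
procedure; `scope = "all"` preserves the alternative.

## Phase-space reconstruction

For each variable the delay tau is the first local minimum of the mutual
information between `x[t]` and `x[t + lag]`, estimated on an equal-width
2-D histogram with `ceiling(sqrt(N))` bins per axis. Three numerical
choices matter:

* **Bias correction.** Under independence the raw histogram MI sits at
  `(r-1)(c-1) / (2N)` nats of pure estimator bias (about half a nat at
  these sizes). That bias is subtracted (clamped at zero). The shift is
  constant across lags — the marginals are the same series — so minima
  positions are untouched, while independent data now score ~0 and fall
  through to `tau = 1`.
* **Smoothing.** A centred 3-point moving average is applied before
  minimum detection; raw curves carry enough jitter to create spurious
  first minima.
* **Fallbacks.** No local minimum: first lag below `1/e` of MI(1).
  MI(1) itself ~0: the series is already independent at lag 1 and
  `tau = 1` is returned, flagged `"independent"`.

The embedding dimension m comes from false nearest neighbours: for each
candidate dimension, the fraction of nearest neighbours whose distance
grows by more than `r_tol = 15` when the next coordinate is added; m is
the first dimension with fraction below 1%, or the argmin if the
threshold is never crossed. Neighbour search uses a Theiler exclusion
window (default tau) — densely sampled flows otherwise pick temporal
neighbours, collapsing the fraction to zero at m = 1 — and a
scale-relative floor (`1e-8 * sd`) on the denominator so machine-precision
duplicates on periodic orbits are not misclassified. On generated data
these choices recover the textbook answers (m = 2 for a noiseless sine,
m = 3 for Lorenz, delay near the quarter period), which is what the
acceptance suite asserts.

The trajectory matrix follows the delay-coordinate layout: entry
`(j, k) = x[k + (j-1) tau]`, giving `N - (m-1) tau` phase points and
`N - (m-1) tau - l` supervised pairs for horizon `l` (one earlier draft of
the sizing arithmetic suggested one fewer pair; hand enumeration confirms
the count formula).

## The CNN-LSTM forecaster

Each supervised sample is one phase point (m delayed coordinates). The
stack is: 1-D convolution along the delay axis (16 channels, kernel 3,
zero-padded to preserve length) -> ReLU -> max-pool (width 2) -> the
pooled feature map read as a short sequence by a single-layer LSTM with
100 units -> linear head predicting the value at `t + l`. The loss is
implemented exactly as the weight-decay objective
`||y - yhat||^2 + lambda ||W||^2` — a *sum* of squared errors plus an L2
penalty (lambda = 0.01) on the weight matrices (convolution kernels, LSTM
input/recurrent matrices, head), not the biases. Training uses Adam
(learning rate 0.01) for 100 epochs on a 9:1 chronological
train/validation split, with inputs and targets standardized internally
(inverted for all reported predictions). If the validation MAPE misses the
accuracy threshold (default 10%, the "highly accurate" band boundary), the
network is reinitialized and retrained, up to 5 attempts, keeping the best.

The whole network — forward pass, backpropagation through the LSTM gates,
pooling argmax routing and convolution, and Adam — is implemented in base
R. This keeps training single-threaded and bit-reproducible under a seed,
and the analytic gradients are verified against central finite differences
in the test suite (agreement to ~1e-8 relative). Problem sizes are chosen
so a full training run takes a couple of seconds: series of 300-450
points, giving ~300-440 supervised pairs. Small conv/LSTM sizes are used
in unit tests; the acceptance suite trains the full default architecture.

Interpretation choices: the "training time step equals the embedding
dimension" statement is read as *LSTM input sequence length = m* (the
pooled delay axis is the sequence); and one model is trained per variable
(the per-variable mapping `G_i`), which keeps each forecaster's input the
variable's own reconstructed state. A joint model over the concatenated
`sum(m_i)` state is deliberately out of scope.

## Comprehensive risk index and levels

Per variable, `W_i(t) = ||x(t)| - x0_bar| / (x_max - x0_bar)` where
`x0_bar` and `x_max` are the mean and maximum amplitude under "normal
conditions" — operationalized as a user-designated reference window
(default: the first 90% of the series). `W_i` is clipped to [0, 1]: the
raw ratio is unbounded when the amplitude exceeds `x_max`, and clipping
keeps the composite interpretable. The composite is the weighted sum
`W_z = sum(W_i p_i)` with non-negative weights summing to 1 — equal by
default (no published weighting method); an entropy-weight helper is
provided as a clearly-labelled extension. Four levels with closed lower
boundaries at 0.75 / 0.5 / 0.25: risk, subsidiary risk, subsidiary safe,
safe. The thresholds are arbitrary but fixed and surfaced in
configuration; no outcome linkage is claimed for the scale.

## PSO-GRNN

The GRNN is Nadaraya-Watson regression with a Gaussian radial basis
kernel: prediction is `sum(y_j K_j) / sum(K_j)` with
`K_j = exp(-d_j^2 / (2 sigma^2))`, max-shifted so underflow cannot zero
the denominator. Its single smoothing factor sigma is selected by particle
swarm optimization: 10 particles, learning factors c1 = c2 = 0.2 (the
protocol states one "learning factor 0.2"; the symmetric reading is the
common convention), constant inertia 0.7, at most 100 iterations or
fitness below 0.001. The printed adaptive-inertia formula *increases* with
iteration, contradicting its own description ("w gradually decreases");
the constant-inertia default sidesteps this, and the `"adaptive"` option
implements the decreasing form
`w = W_max - (W_max - W_min) * tan((I / I_max) * pi / 4)` as a deliberate
correction.

"Fourfold cross-validation" with a "9:1 split" is resolved as an outer 9:1
chronological holdout plus inner 4-fold CV mean squared error as the PSO
fitness; the final model refits on the full training portion with the
selected sigma. Inputs are standardized internally, so the default sigma
bounds [1e-3, 1] refer to the standardized scale — which makes the
*standardized* sigma scale-invariant and the effective bandwidth
`sigma * sd(X)` scale-equivariant (the test asserts this form).
Risk-level regression targets are the numeric `W_z` values; the discrete
level is derived afterwards by thresholding, since no numeric coding of
"risk level" is published.

The published optimal fitness values (0.0052 / 0.0089) and smoothing
factors (0.0753 / 0.0868) depend on the private hospital series and are
not reproduction targets; the machinery and its properties (grid-search
agreement, monotone best-fitness trace, kernel limits) are.

## Forecast evaluation

MAPE is `100/N * sum(|y - yhat| / |y|)` with zero targets excluded (and
counted in a warning). MASE is implemented **as printed**: mean absolute
error divided by the mean absolute deviation about the mean — this is
*not* the conventional naive-forecast-scaled MASE; the conventional form
is available behind `conventional = TRUE`, off by default. Quality bands
on MAPE: below 10% "highly accurate", 10-20% "good", 20-50% "reasonable",
50%+ "weak", lower-inclusive boundaries. Model comparison reports the
relative MAPE reduction of the best versus the worst model and each
model's MASE as a ratio to the best; on the published four-model table
these reproduce the printed 58.75% reduction and 2.25 / 2.51 / 1.75
ratios.

## Known limitations

* The synthetic cohort cannot validate the score's clinical performance —
  only the arithmetic and the recovery of its own generating structure.
  The published AUC (0.846) and absolute forecast errors (MAPE 9.739)
  require the private patient data and are not reproduction targets.
* The histogram MI estimator is crude by design (the bin rule is fixed);
  it is adequate for delay selection on the provided systems, not a
  general-purpose MI tool.
* The four-level risk scale has no outcome linkage; thresholds are
  conventions.
* `positive_lr` is the positive likelihood ratio; one published passage
  labels the same quantity "PLR (platelet-to-lymphocyte ratio)". The
  package keeps the likelihood-ratio reading and the blood-count PLR as
  separate concepts.
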