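---
title: "Two-stage pretraining of laboratory-trajectory forecasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage pretraining of laboratory-trajectory forecasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labprogress)
```

## The problem

Routine laboratory markers (cholesterol ratios, LDL-c, fasting glucose,
white-cell count, uric acid) are measured irregularly: follow-up visits are
nominally scheduled every three months, but patients skip or shift visits,
and record lengths vary from one to many years. Cohorts with a rare,
episodic outcome — here, target vessel revascularization (TVR) after a
coronary intervention — are too small to learn temporal dynamics from
directly: each patient contributes a single visit. `labprogress`
implements a transfer strategy: learn marker dynamics from a large
longitudinal cohort ("pretext"), then use the frozen forecasters to embed
single-visit patients of the small cohort ("downstream") into a
progress-representation space where a conventional classifier separates
events from non-events.

## Interpolation onto the monthly grid

Observations of one patient and marker are anchors $(t_i, y_{t_i})$ on an
integer month grid. Missing months between the first observation $t_0$ and
the *second-to-last* observation $t_m$ are filled by one of three
interpolants: linear (the gradient of the bracketing pair), shape-preserving
piecewise cubic Hermite (PCHIP), or the global barycentric Lagrange
polynomial. The last observation $t_n$ is never interpolated over — it is
reserved as a forecasting target. All methods reproduce anchor values
exactly; linear and PCHIP stay within the bracketing node values, the
global polynomial may overshoot (this is tested as a documented
non-invariant, and node counts are capped at 50 for numerical stability,
with values floored at zero when assembling features, since laboratory
measurements are non-negative).

For PCHIP the node derivative is the weighted harmonic mean of adjacent
secant slopes $d_i, d_j$ with weights $w_1 = 2 h_{next} + h_{prev}$,
$w_2 = h_{next} + 2 h_{prev}$, set to zero when the slopes change sign or
vanish. Zeroing is applied to the *derivative*, not the node value: zeroing
values would violate the interpolation condition. Endpoint derivatives use
the standard one-sided three-point rule with sign clipping, so the
interpolant coincides with reference implementations (`pracma::pchip`
agrees to $10^{-9}$ in the test suite).

## Framing

The filled timeline is cut into sliding windows of $r + 1 = 13$ monthly
points ($r = 12$ months, the horizon over which stent-related outcomes are
typically assessed). Stage-1 frames start at every month $i$ with
$i + r \le m - 1$ and predict the value at $i + r + 1$; a series whose
filled span fits inside one window yields no frames. Each window month
carries a *certainty bit* (real observation vs interpolation), and a frame
is kept only if it holds at least `certain_min` real observations
(explored 0–5; with 3-monthly visits a 13-point window holds at most 5).
The stage-2 sample is the final real-anchored window $t_m - r .. t_m$
paired with the last real observation as target, a gap of
$g = t_n - t_m - 1$ months ahead; samples with $g > r/2$ are excluded, so
forecasts are evaluated without interpolation support beyond half a
window.

## Encoding

Each window month is a 5-vector: `log1p` value, `log1p` age, sex bit,
certainty bit, and a discrete code (threshold category scaled to [0, 1]).
`log1p` keeps features non-negative and requires no dataset statistics, so
it cannot leak across splits. The clinical cut-points behind the discrete
code are configurable (`default_thresholds()` ships plausible defaults;
they are package defaults, not clinical assertions). The discrete level is
encoded as a single scaled ordinal rather than one-hot so that the feature
width stays 5, matching the network's input width; a 3-level one-hot would
break the stated 5-feature geometry.

## The model and its two-stage training

Per marker, the forecaster is a bidirectional LSTM (5 hidden nodes per
direction), a condensing affine layer mapping the concatenated 10-vector
back to the 5-dimensional feature width (ReLU after each layer), and a
regressor (5 → 2 → 1 with ReLU in between). The condensing layer's output
width equals the input width by construction — this closes the
autoregressive loop: the final step's condensed vector is read as the
predicted feature vector of the next month.

*Stage 1* trains on interpolated frames: one pass, MSE against the
next-month normalized value. *Stage 2* is autoregressive self-supervision
on non-interpolated windows: the model's own predicted value is appended
(certainty 0, discrete code recomputed from the denormalized prediction,
age/sex carried forward — age changes by at most half a year over
$g \le 6$), the window slides, and after $g + 1$ passes the prediction is
scored against the last real observation. Batches with heterogeneous gaps
are processed jointly to the largest gap with per-sample selection, which
equals the per-sample loop exactly (tested). The loss in both stages has
two terms at the selected step: the regressor's error and the condensed
value channel's error against the same target. The second term is what
makes the condensed output an actual next-value prediction; without it the
channel that rollout feeds back is unconstrained and autoregressive
forecasts diverge. Intermediate rollout steps receive no loss.

Training uses Adam for 50 epochs per stage, batch size 64. The default
learning rate is 1e-2: with `log1p`-scale targets around 4–5 and the fixed
50-epoch schedule, smaller rates cannot traverse the output scale on
desk-scale cohorts. Two safeguards address optimization pathologies we
observed with this tiny recurrent architecture on unscaled `log1p`
inputs: global gradient-norm clipping (default 1; backpropagation
through the rollout occasionally produces a step large enough to kill a
ReLU unit permanently), and seeded random restarts (default 3) for any
stage that begins from random weights — each candidate trains a burn-in
fifth of the budget and the lowest-loss one continues, because a
noticeable fraction of initializations otherwise settle into a
mean-prediction basin where the value pathway is never used. Biases
feeding a ReLU are initialized slightly positive for the same reason.
Stages refining an already-trained model never re-initialize. Four
regimes are available: `supervised` (stage 1 only), `ssl` (stage 2 from
fresh weights), `two_stage` (stage 1 then stage 2) and `hybrid`
(interleaved batches under one optimizer state). Because one stage-1
epoch performs many more optimizer updates than one stage-2 epoch,
regime comparisons use `matched_budget_configs()`, which equalizes the
total number of Adam updates across regimes at the two-stage schedule's
budget.
Zero-epoch stages make the regimes coincide exactly (`two_stage` with no
stage 2 *is* `supervised`, with no stage 1 *is* `ssl`), which the tests
exploit as equivalence checks. The network and its exact reverse-mode
gradients are implemented in the package — compiled inner loops with a
pure-R reference implementation kept as a numerical oracle — and
verified against central finite differences at tolerance 1e-4 in the
suite.

Evaluation follows the study protocol: patient-level 80:20 split per
repetition, 5-fold cross-validation inside the training split, fold models
scored by $R^2$ of forecasting held-out patients' last real observation
from their stage-2 window. Since the split interaction is under-specified,
we train on each fold complement and score every fold model on the outer
20%; reported values are per-fold-then-averaged. All interpolation is
per-patient, so test patients never borrow information.

## The synthetic cohort generator

The real cohorts are private; the generator emulates their statistical
structure rather than their distributions. Per patient and marker the
latent trajectory is $b \exp(s\,t/12 + e_t)$ with log-baseline
$b \sim \mathcal{N}(\mu_m, \sigma_m)$, per-year log-slope
$s \sim \mathcal{N}(0, 0.1)$, and AR(1) log-noise $e_t$ (autocorrelation
0.7, stationary sd 0.05 by default) — the simplest positive-valued process
with persistent individual trends. Visits occur at months
$\{0, 3k \pm 1, T\}$ with 15% independent dropout of interior visits;
first and last visits are always kept; spans are uniform on 18–48 months
(at least a year, as in the study design). Age is
$\mathcal{N}(57, 12)$ clipped to [30, 95], sex Bernoulli(0.65).

The downstream generator draws one value per marker per patient.
Negatives come from the stable baseline regime; positives have their
log-scale dispersion inflated by $1 + \text{effect\_size}$ with the mean
unchanged, emulating accumulated divergent trends (cases scatter,
controls cluster). Both classes draw the gap $g$ from the same
geometric-like law (mean ≈ 28 months, matching an occurrence duration of
about 2.3 years), clipped to [1, 72]. Giving negatives a longer censoring
law would be more literal but would leak the label through rollout depth;
with a shared law, `effect_size = 0` makes the classes identical in
distribution, which the suite verifies as a no-leakage null. What the
generator deliberately does *not* emulate: real marker distributions,
inter-marker physiological correlation, informative visit timing, and
assay differences between institutions — so passing tests demonstrate the
pipeline's mechanics and its directional properties, not clinical
performance.

## Transfer

The six trained forecasters are frozen. A downstream record is expanded
into a window by carrying its single value back across all 13 months with
the certainty bit set only at the last month (configurable: zero-fill is
also available); the window is rolled out to the patient's own horizon
($g$, or $\lfloor g/2 \rfloor$ — the iteration before the intended event).
Per patient, the condensed embeddings concatenate to a 30-vector
(`Progress_emb`) and the scalar outputs to a 6-vector (`Progress_out`);
the normalized raw features (6 values + age + sex) are the baseline.
After exact downsampling of negatives (42 positives + 42 sampled
negatives by default), four classifier families — gradient-boosted trees,
RBF SVM, logistic regression, k-nearest neighbours, all with library
defaults and fixed seeds — are scored by repeated stratified 5-fold
cross-validation (five repetitions), reporting AUROC, accuracy,
sensitivity, specificity, precision, F1, and the mean pairwise Cohen's
kappa between the classifiers' pooled held-out predictions as the
agreement measure.

## Numerical choices and degenerate inputs

* Queries outside the observed span are errors — the interpolation module
  never extrapolates; the forecaster is the extrapolation mechanism.
* A value equal to a discretization cut-point goes to the upper bin.
* Two-point series degenerate: the second-to-last anchor equals the
  first; such series yield no frames and no stage-2 sample.
* $R^2$ is undefined (an error) when the truths are constant.
* Ties in barycentric nodes are rejected; node weights are rescaled by
  the span to avoid overflow.
* Seeds: every stochastic step (generation, initialization, batching,
  splits, downsampling, classifier fits) derives from explicit integer
  seeds; repeat/fold seeds are small linear offsets of the base seed.

## Problem sizes used in the shipped checks

The package's own evaluation scripts use desk-scale cohorts chosen to
exercise every code path at sensible statistical power: 200 patients for
noise-free trend-recovery (held-out $R^2 \ge 0.9$), 80 patients and five
seeded repetitions for the regime comparison, 60 pretext patients and the
full 42/441 downstream cohort for the transfer study. These sizes are the
package's defaults for its examples and acceptance script; the method
itself scales linearly in patients and markers.

## What the synthetic studies show — and what they do not

Two of the pipeline's directional claims are tied to properties of the
original private cohorts that this deliberately simple generator does
not possess, and the package's acceptance checks report them honestly
rather than calibrating them into existence.

*Regime ordering.* On real, messy laboratory data the original study
found self-supervised and two-stage training far ahead of supervised and
hybrid training. On the generator's smooth trend-plus-AR(1)
trajectories, interpolated next-month targets are informative rather
than misleading, so supervised pretraining transfers well to the gapped
forecasting task and the ordering does not reproduce; our diagnostics
show the supervised collapse re-appears exactly when the condensing
layer's feedback channel is left untrained, which the two-stage loss
repairs. The acceptance suite runs the comparison at matched update
budgets and asserts the published direction; the regime means it
computes are also written by `scripts/acceptance.R`.

*Transfer gain.* For episodic records the progress representation is a
deterministic function of the same single-visit features (plus the gap,
which reaches the classifier only through rollout depth), so it cannot
exceed the raw features' information content; any advantage must come
from geometry that suits the four classifier families. On this
generator the iterated map folds extreme values onto fixed-point
plateaus — classifier agreement (kappa) typically rises, mirroring the
published direction — but mean accuracy does not surpass the raw
features. Both quantities are recomputed and reported by the
acceptance script.

## Known limitations

* Learned dynamics are per-marker; no joint multi-marker model.
* The downstream window expansion from a single visit is an invented
  construction (the original pipeline does not specify one); both
  carry-back and zero-fill are provided so the choice is testable.
* `Progress_emb`/`Progress_out` are representations; inverse-normalizing
  `Progress_out` gives an indicative, not calibrated, future value.
* Polynomial (barycentric) interpolation degrades on long series; it is
  retained for comparison, as the weakest of the three methods.
* No GAN-style imputation, survival modelling, or neural downstream
  classifier — small downstream cohorts favour the four classical
  families used here.
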