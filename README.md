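# labprogress

Irregular longitudinal laboratory series — cholesterol ratios, LDL-c,
fasting glucose, white-cell count, uric acid — carry disease-progress
information that small episodic cohorts cannot learn on their own.
`labprogress` implements a two-stage pretraining pipeline for per-marker
trajectory forecasters and a frozen-representation transfer stage for
downstream binary event classification (the motivating case: predicting
target vessel revascularization after coronary intervention from a single
visit's laboratory panel). It is aimed at biostatisticians and clinical
ML researchers who want a fully seeded, end-to-end testable reference
implementation with a synthetic cohort generator standing in for private
EHR data.

## Method

For one patient and marker with observations $y_{t_0}, \dots, y_{t_n}$ on
an integer month grid, months between $t_0$ and the second-to-last
observation $t_m$ are filled by linear, PCHIP or barycentric
interpolation. Windows of $r+1 = 13$ monthly 5-feature vectors
(`log1p` value, `log1p` age, sex, certainty bit, discrete threshold code)
are formed: stage-1 frames at every start $i$ with $i + r \le m - 1$,
targeting month $i+r+1$; and one stage-2 sample per patient — the window
ending at $t_m$, targeting the real observation $y_{t_n}$ at gap
$g = t_n - t_m - 1 \le r/2$.

The forecaster is a bidirectional LSTM (hidden size 5) with a condensing
affine layer back to the 5-feature input width (ReLU after each layer)
and a 5→2→1 regressor. Stage 1 is supervised next-month prediction on
interpolated frames; stage 2 is autoregressive self-supervision — the
model's own predictions are appended to the window for $g+1$ passes and
the final prediction is scored against $y_{t_n}$ (MSE, Adam, 50 epochs
per stage). Training regimes `supervised`, `ssl`, `hybrid` and
`two_stage` are compared by held-out patient-level $R^2$. For transfer,
the six frozen per-marker models embed single-visit records (value
carried back across the window, certainty set only at the last month,
rollout to the patient's own gap); the concatenated regressor outputs
(`Progress_out`, 6-vector) and condensed embeddings (`Progress_emb`,
30-vector) feed gradient-boosted trees, an RBF SVM, logistic regression
and k-NN, scored by repeated stratified cross-validation plus the mean
pairwise Cohen's kappa between classifiers.

The network, its exact backpropagation (verified against finite
differences) and the rollout are implemented in the package, with the
inner loops in compiled code and a pure-R reference used as a test
oracle.

## Worked example

```r
library(labprogress)

cfg <- cohort_config(n_patients = 60, seed = 1001, noise_sd = 0.08)
cohort <- simulate_pretext_cohort(cfg)

tc <- train_config(seed = 1)                       # 50 epochs/stage, Adam
frames  <- stage1_dataset(cohort$observations, cohort$patients, "glucose_ac", tc)
samples <- stage2_dataset(cohort$observations, cohort$patients, "glucose_ac", tc)
model <- train_glp(frames, samples, tc)            # two-stage by default

glance(model)
#> # A tibble: 1 x 5
#>   marker     stage     n_params  seed final_loss
#>   <chr>      <chr>        <int> <int>      <dbl>
#> 1 glucose_ac two_stage      510  1001     0.0916

evaluate_forecast(model, samples)
#> [1] 0.699921
```

The final training loss sums the regressor's and the condensed value
channel's squared errors on the normalized (log1p) scale (the seed shown
is the winning random restart's). The forecast $R^2$ of 0.70 says that
rolling the model out to each patient's own gap explains most of the
between-patient variance in the last held-back observation of this noisy
cohort.

Downstream transfer on a synthetic episodic cohort:

```r
d <- simulate_downstream_cohort(cfg, effect_size = 1)   # 483 records, 42 positive
b <- balance_downsample(d, seed = 1)                    # 84 records, balanced
markers <- cfg$markers
models <- lapply(markers, function(mk) train_glp(
  stage1_dataset(cohort$observations, cohort$patients, mk, tc),
  stage2_dataset(cohort$observations, cohort$patients, mk, tc), tc))
names(models) <- markers
reps <- extract_representations(models, b, horizon = "g")
run_classifiers(as.matrix(reps[, grep("^out_", names(reps))]),
                reps$event_label, seed = 1)
```

which prints the per-classifier AUROC/accuracy/sensitivity/specificity
table and the mean pairwise kappa. `snapshot_export()` +
`plot_snapshot()` visualize how stable patients' denormalized outputs
converge under rollout while diverging patients scatter.

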