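# elstm

Stress classification from tabular health-survey variables with a
feature-attention **enhanced LSTM (E-LSTM)**, implemented from scratch in R
and verified end to end.

Population surveys such as KNHANES VI record, for each respondent, a small
set of physical-activity and lifestyle variables — age, gender, height,
weight, sleep duration, pulse rate, systolic/diastolic blood pressure, BMI,
drinking and smoking — together with a self-reported stress level collapsed
to two groups (low/high). `elstm` is for methodologists who want a fully
inspectable, reproducible implementation of an attention-based recurrent
classifier for this kind of tabular two-group problem, including the
statistics around it:

* **Synthetic cohorts** — `generate_cohort()` draws two-group cohorts whose
  group means, category proportions, sizes (640/633) and study imbalance
  (651 high / 2529 low via `generate_imbalanced_study()`) match the
  published stress-study structure, so everything runs with no data access.
* **Feature screening** — `screen_features()` applies two-sided Welch
  t-tests (continuous) and uncorrected Pearson chi-square tests (binary) at
  p < 0.05, reproducing the published contingency-table p-values exactly
  (gender 0.001, drinking 0.004, smoking 0.000).
* **The model** — `elstm_forward()` chains a bidirectional *peephole* LSTM
  encoder over the feature sequence, dot-product attention over the
  per-feature states, a peephole decoder fed by the attention context, and
  a dense + sigmoid head. Each screened feature is one time step (T = 9
  after default screening), so attention is a distribution over features:

  i, f = σ(W [C₍ₜ₋₁₎, h₍ₜ₋₁₎, xₜ] + b)  C̄ₜ = tanh(W_c [h₍ₜ₋₁₎, xₜ] + b_c)
  Cₜ = f ⊙ C₍ₜ₋₁₎ + i ⊙ C̄ₜ  o = σ(W_o [Cₜ, h₍ₜ₋₁₎, xₜ] + b_o)  hₜ = o ⊙ tanh Cₜ

  eₖ = cᵀhₖ  wₖ = softmax(e)ₖ  context = Σₖ wₖ hₖ

* **Training** — `fit_elstm()` minimizes binary cross-entropy + L2 with
  Adam (β₁ = 0.9), dropout on the encoder states, seeded stratified
  splits and hand-written backpropagation whose every gradient is verified
  against central differences (`check_gradients()`, worst relative error
  ~1e-6).
* **Evaluation** — confusion matrices with high stress as the positive
  class and exact accuracy/precision/recall/F1 (`classification_metrics()`),
  plus the published benchmark confusion counts as a fixture
  (`benchmark_confusions()`).
* **Pipeline & CLI** — `run_pipeline()` chains
  simulate → screen → train → evaluate with one global seed and writes all
  artifacts plus a manifest; `inst/cli/elstm-cli.R` exposes the same stages
  as shell subcommands.

## Worked example

```r
library(elstm)

cohort <- generate_cohort(default_cohort_spec(), seed = 42)
screen_features(cohort, alpha = 0.05)
#> Feature screening at alpha = 0.05
#>        variable       kind statistic p_value selected
#>          gender chi-square    10.077   0.002     TRUE
#>             age          t    12.208   0.000     TRUE
#>          height          t    -4.140   0.000     TRUE
#>          weight          t    -3.338   0.001     TRUE
#>  sleep_duration          t     6.159   0.000     TRUE
#>      pulse_rate          t    -6.075   0.000     TRUE
#>             sbp          t     6.711   0.000     TRUE
#>             dbp          t    -0.860   0.390    FALSE
#>             bmi          t     1.400   0.162    FALSE
#>        drinking chi-square     4.679   0.031     TRUE
#>         smoking chi-square    27.570   0.000     TRUE
#> Selected: gender, age, height, weight, sleep_duration, pulse_rate, sbp, drinking, smoking
```

The screening stage recovers the nine informative variables and rejects
the two planted near-nulls (DBP, BMI), mirroring the published
significance pattern. Training on a strongly separated validation cohort
shows the loop actually learns:

```r
cohort <- generate_cohort(separable_cohort_spec(200, 200), seed = 7)
model <- fit_elstm(cohort,
                   features = screen_features(cohort)$selected,
                   config = training_config(epochs = 60, batch_size = 64,
                                            learning_rate = 0.01,
                                            dropout_rate = 0, n_hidden = 8),
                   seed = 7)
val <- cohort[model$split$val, ]
cm <- confusion_counts(val$stress, predict(model, val, type = "class"))
classification_metrics(cm)
#> accuracy:  100.00%
#> precision: 100.00%
#> recall:    100.00%
#> F1:        100.00%
```

Here the 80 held-out records (40 per group) are classified perfectly —
expected on this fixture, whose group shifts are many standard deviations
wide; on realistically calibrated cohorts the two groups overlap heavily
and accuracy is modest, as it is on the real survey.

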