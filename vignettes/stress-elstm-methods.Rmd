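---
title: "Methods: feature-attention E-LSTM stress classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-attention E-LSTM stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elstm)
```

## The problem

Self-reported stress in population health surveys such as KNHANES VI is
associated with a handful of physical-activity and lifestyle variables:
age, gender, height, weight, sleep duration, pulse rate, systolic and
diastolic blood pressure, BMI, drinking and smoking. `elstm` implements a
classifier that treats these tabular variables as a short ordered sequence
and lets an attention mechanism decide, per subject, which variables drive
the low-stress / high-stress decision. The package contains the complete
workflow — synthetic cohort generation, univariate feature screening, the
recurrent model with hand-written backpropagation, training and
evaluation — so that every stage is testable without access to the
original survey.

## Model

### Peephole memory cell

The core cell is an LSTM memory block with peephole connections. With
input $x_t$, hidden state $h_{t-1}$ and memory cell $C_{t-1}$:

$$
\begin{aligned}
i_t &= \sigma(W_i\,[C_{t-1}, h_{t-1}, x_t] + b_i), &
f_t &= \sigma(W_f\,[C_{t-1}, h_{t-1}, x_t] + b_f), \\
\bar C_t &= \tanh(W_c\,[h_{t-1}, x_t] + b_c), &
C_t &= f_t \odot C_{t-1} + i_t \odot \bar C_t, \\
o_t &= \sigma(W_o\,[C_t, h_{t-1}, x_t] + b_o), &
h_t &= o_t \odot \tanh(C_t).
\end{aligned}
$$

The output gate reads the *current* cell $C_t$, the standard peephole
convention. With `peephole = FALSE` the gates act on $[h_{t-1}, x_t]$
only, which recovers the classical LSTM cell; the classical memory update
is implemented as $C_t = f_t \odot C_{t-1} + i_t \odot \bar C_t$ (the
usual recursion on the previous cell, not on the previous input).
Zeroing the $C$-columns of a peephole cell's gate matrices makes it
step-for-step identical to the classical cell — a structural identity the
test suite verifies to $10^{-12}$.

### Sequence construction

Each screened feature is one time step carrying a single standardized
scalar, in the fixed schema order; after default screening the sequence
has $T = 9$ steps of width $m = 1$. This is the reading under which
"feature attention" is meaningful: the attention distribution is a
distribution over features. The alternative — one step with a 9-wide
input — would make the bidirectional encoder and the attention softmax
degenerate to a single position, so it was rejected. Continuous features
are z-scored with training-set mean/SD; binary features are mapped to
$\{0,1\}$ and z-scored identically; the fitted scaler is stored with the
model and saved in checkpoints.

### Encoder, attention, decoder, head

The pre-feature-attention encoder runs a forward and a backward peephole
cell over the sequence from zero states; at each position $k$ the two
directional hidden vectors are combined through a learned projection,
$h_k = f(V\,[\vec h_k ; \overleftarrow h_k] + k)$. The combiner
nonlinearity $f$ is `tanh`, consistent with every other candidate
nonlinearity in the architecture. The states handed to attention are
these combined states rather than the raw directional ones, since the
attention layer is defined on the encoder's (single) hidden unit per
position.

Attention scores each position by a dot product with the decoder memory
vector, $e_k = c^\top h_k$, normalizes with a max-subtracted softmax over
the $T$ positions, and forms the context $o = \sum_k w_k h_k$. The
post-feature-attention decoder is a peephole cell (input width $n$)
started from the zero state; at each decoder step the attention context
computed from its current memory vector is the step input. One decoder
step is the default — the architecture does not prescribe a decoder
length, and a single step already consumes the full attention summary —
but `steps` is exposed for experimentation, with attention recomputed
from the updated memory vector at every step. A consequence worth
noting: at the first decoder step the query is the zero memory vector, so
the attention weights are exactly uniform and the context is the plain
average of the per-feature states; feature-differentiated attention
distributions appear from the second step onward (`steps >= 2`), when the
query carries learned state. A dense weight vector and
sigmoid turn the final hidden vector into the high-stress probability;
ties at the 0.5 threshold classify as `high`, the clinically relevant
minority class.

### Parameter count

`count_parameters()` reports the exact number of trainable scalars from
the shape rules (for hidden size 1 and scalar inputs: 50). The nominal
complexity figure $7(n^2 + nm + n)$ quoted for this architecture in the
literature does not follow from any consistent shape arithmetic; it is
surfaced by `nominal_parameter_count()` for reference only.

## Training

The loss is mean binary cross-entropy plus an L2 penalty
$\lambda_r \sum w^2$ over weight matrices (biases and the combiner bias
excluded), with probabilities clipped to $[10^{-7}, 1-10^{-7}]$ before
the logarithm. Gradients are computed by hand-written reverse-mode
backpropagation through head, decoder, attention, combiner and both
encoder directions (full BPTT); `check_gradients()` re-derives every
gradient by central differences of the forward pass and reports the worst
relative disagreement, using the denominator
$\max(|a|, |n|, 10^{-4})$ so that negligibly small gradients are compared
absolutely (a pure ratio would amplify floating-point noise at the
$\sim 10^{-10}$ level of the difference quotient).

The optimizer is Adam with decay factor $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$ and bias-corrected moments.
Configuration preset 1 (the default) is learning rate $5\times10^{-4}$,
batch size 768, dropout 0.2, 150 epochs, $\lambda_r = 10^{-5}$,
momentum 0.1; preset 2 is $3\times10^{-4}$ / 1024 / 0.3 / 100 / momentum
0. Two of these fields deserve comment. The momentum value is recorded
for fidelity to the published configuration but is inert: that
configuration simultaneously names Adam as the optimizer, and Adam has no
separate momentum hyperparameter (a plain SGD optimizer is available via
`optimizer = "sgd"`). Likewise a stray "$w = 0.001$" norm coefficient
appears alongside $\lambda_r = 10^{-5}$ in the source description of the
loss; it is uninterpretable as stated and $\lambda_r = 10^{-5}$ is used.

Dropout (inverted scaling, training only) is applied to the encoder's
combined per-feature states $h_k$ — the published setting says only "for
the LSTM layer", and the encoder output is the layer boundary at which
dropout does not interfere with the recurrent state recursions. The
train/validation protocol is likewise unstated upstream; a seeded
stratified 80/20 split is used and exposed via `val_fraction`. All
randomness (split, initialization, shuffling, dropout masks) derives from
one integer seed through fixed sub-streams, so fits are bit-reproducible.

Weights initialize Glorot-uniform with zero biases and forget-gate biases
of 1 — not part of the published description, but stated here explicitly
because reproducibility requires *some* fixed convention and this is the
field's standard one.

## Feature screening

Continuous candidates are screened with the two-sided Welch t-test,
binary ones with the Pearson chi-square test on the 2×2 table *without*
Yates continuity correction, selecting at $p < 0.05$ with no multiplicity
correction. Two choices here are data-driven: the uncorrected chi-square
is the only variant that reproduces the published p-values of the
gender (0.001), drinking (0.004) and smoking (0.000) tables — with the
correction, drinking comes out at 0.005 — and Welch is chosen over the
pooled-variance Student test because the published description does not
say which was used and the printed t-test p-values are not recomputable
(no SDs are printed); the assumption-lighter default is taken.
p-values print in fixed 3-decimal notation in the summary layout (so
$6.6\times10^{-6}$ displays as 0.000) while full precision is retained in
the report object.

## The synthetic cohort generator

`generate_cohort()` emulates a two-group case/control cohort with the
published group structure: group sizes 640/633 (the sums of the printed
gender counts), group means for the eight continuous variables and
second-category proportions for the three binary ones equal to the
printed values, labels assigned by group membership. Continuous draws use
truncated normal distributions (inverse-CDF sampling) with physiologic
bounds — age is confined to the surveyed 18–75 range, sleep to 1–14 h,
and so on — and the location parameter is re-solved numerically so that
the *truncated* mean equals the target group mean; naive truncation would
bias age by more than 3 years against the 75-year cap. BMI is never
sampled: it is recomputed as weight/(height/100)² after sampling so the
derived-variable identity holds exactly in every record.
`generate_imbalanced_study()` reproduces the full-study imbalance of
651 high-stress versus 2529 low-stress records.

Group SDs are not published anywhere, so they are package choices. They
were set by an a-priori power calculation with the goal of reproducing
the published significance pattern in expectation at n = 640/633 — the
seven informative continuous variables significant, DBP and BMI not:
age 16, height 6, weight 3.5, sleep 1.3, pulse 9, SBP 16, DBP 25
(noncentralities ≥ 4 for the informative variables, ≈ 0.8 for the DBP
null). Two consequences are worth stating plainly. First, the weight and
height dispersions are tighter, and the DBP dispersion wider, than in a
real adult population — the generator reproduces the published *decision
pattern*, not survey-realistic marginal variances. Second, the exact
nine-variable recovery rate has a hard ceiling of about 0.68 regardless
of any SD choice, because the powers of the gender (≈ 0.91) and drinking
(≈ 0.83) chi-square tests are fixed by the published proportions and
group sizes, and each of the two planted nulls is falsely selected with
probability near the 0.05 test level. Observed recovery across seeded
replicates is around 0.4–0.6, which is what that arithmetic predicts.
Passing tests on these cohorts therefore demonstrate the pipeline's
statistical behavior under the published effect sizes, not performance on
real KNHANES records, which carry survey weights, missingness,
correlations between variables and non-normal marginals that the
generator deliberately does not model.

## What the tests do and do not show

The gradient check (hidden size 3, four steps, batch 5, central
differences with step $10^{-6}$, relative tolerance $10^{-5}$) is the
load-bearing test of the model core. Attention normalization, the
peephole-to-classical reduction, seeded determinism and the loss worked
values are exact properties. The learnability check trains on a strongly
separated 400-record synthetic cohort (hidden size 8, 60 epochs, batch
64, learning rate 0.01, dropout off — at the preset learning rate and
batch size, 60 epochs provide only ~60 Adam steps, far too few parameter
movement for any configuration to learn, so the fixture uses a faster
loop) and requires ≥ 90% training accuracy for most seeds.

The published headline performance (75.54% accuracy, 74.26% precision,
72.99% recall, 74.58% F1) is *not* a package target: it depends on the
real survey data, unstated splits and stochastic training, and it is
internally inconsistent with the published confusion-matrix counts, which
imply 83.9% accuracy and 92.4% precision for the same model. The package
ships those counts as a plain-text fixture (`benchmark_confusions()`) and
recomputes metrics from them, making the inconsistency visible rather
than resolving it; undefined metrics (zero denominators) are reported as
`NA` with a warning, never silently as 0.

Problem sizes throughout the suite are deliberately small — cohorts of a
few hundred for training checks, $10^4$ per group for calibration checks,
$10^5$ resamples for the permutation oracle — chosen as the smallest
sizes at which each property is sharply testable.

## Known limitations

* Single-threaded R implementation of training; fits at the full preset
  settings take tens of seconds on a cohort of ~1300, and the package is
  not intended for large-scale training.
* Binary stress only; the four-level questionnaire item the survey
  collapses from is out of scope.
* No survey weights, no missing-data handling beyond row dropping at CSV
  read, no class re-weighting despite the study imbalance (none was used
  upstream).
* Per-step input width is fixed at 1 in the public forward pass; the cell
  layer supports general widths.
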