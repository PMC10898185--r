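---
title: "Methods: genetic feature selection with a deep network for sinus morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic feature selection with a deep network for sinus morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Frontal and maxillary sinuses are resistant to trauma, which makes their
dimensions useful for forensic profiling when other skeletal structures are
unavailable. From CBCT imaging one obtains, per subject, twelve measurements:
length, width, height and volume of the frontal sinus (FSL, FSW, FSH, FSV)
and of the right and left maxillary sinuses (RMSL/RMSW/RMSH/RMSV,
LMSL/LMSW/LMSH/LMSV). Three estimation tasks are supported:

* **sex classification** (binary, F/M),
* **age-group classification** over four contiguous bins,
  A = [18, 25], B = [26, 33], C = [34, 41], D = [42, 50] years
  (ages above 50 are clamped into D with a warning, so cohorts whose stated
  range extends a year or two past 50 remain ingestible),
* **age regression** (years, continuous).

`gadnn()` implements a hybrid estimator: a genetic algorithm (GA) searches
binary feature masks over the twelve measurements, the fitness of a mask
being the held-out accuracy of a fixed deep neural network (DNN) trained on
the masked features; the final network is retrained on the selected subset.

## Pipeline and its ordering

For classification the stages are: age grouping (age task only) → SMOTE
oversampling → min–max normalization → one-hot encoding → stratified 80/20
split → optional GA selection → final DNN → test-set report.

Two orderings of SMOTE relative to the split are provided:

* `smote_order = "paper"` (default) oversamples the **whole** dataset before
  splitting. This replicates the original protocol, but it is leaky: a test
  row's synthetic interpolants can land in training, which inflates apparent
  accuracy.
* `smote_order = "safe"` splits first and oversamples the training partition
  only. No synthetic row can reach the test partition (the split bookkeeping
  records this). This is the recommended setting whenever the goal is an
  honest generalization estimate.

Regression never applies SMOTE: interpolating class members is meaningless
for a continuous target.

### SMOTE

Each class is raised to the size of the largest class. A synthetic row is
`x + u (x_nn − x)` with `x` a real minority member, `x_nn` one of its `k = 5`
nearest same-class neighbours (Euclidean distance on the raw, pre-scaling
features — SMOTE precedes normalization in the pipeline order), and
`u ~ U[0, 1]`. `k = 5` is the canonical default from the original SMOTE
formulation; classes smaller than `k + 1` reduce `k` to class size − 1 with a
warning, and singleton classes are an error. Age is interpolated along with
the features (both parents lie in the same group, and the group intervals
are convex, so the label is preserved); the seed parent donates the sex of a
synthetic row.

### Normalization, encoding, split

Min–max bounds are fitted on training rows only and applied unchanged to the
test rows, which may therefore fall outside [0, 1] (no clipping); a constant
training feature maps to 0. Class labels are one-hot encoded; decoding is by
argmax with exact ties broken toward the lowest class index. The 80/20 split
is stratified by the task label so every class appears on both sides.

## The network

The architecture is fixed: eight dense trunk layers of widths
1024–512–256–128–64–32–16–8 and a linear output head (4 units for age
groups, 2 for sex, 1 for regression) — nine main layers in all; only the
input width changes when the GA drops features. Each trunk layer is followed
by batch normalization, its activation, and dropout. Trunk layers 1–7 use
ReLU, `f(x) = max(x, 0)`; trunk layer 8 applies softmax,
`f(x_i) = e^{x_i} / Σ_j e^{x_j}` (computed with max-subtraction so large
inputs cannot overflow). We implement this stacking literally — softmax on
the eighth trunk layer, then a linear head with no further nonlinearity, and
classification decoded by argmax of the head outputs; `train_config(head =
"softmax")` offers the conventional alternative of a softmax output layer.
Batch normalization and dropout are applied to trunk layers only — a
batch-normalized *output* layer would rescale predictions to standardized
units, which is not meaningful for either the one-hot targets or the age
head.

The loss is mean squared error between the network output and the one-hot
(or raw) target, optimized by plain stochastic gradient descent for 100
epochs by default. The remaining hyperparameters are not dictated by the
method and are artifact defaults, all overridable through `train_config()`:

| parameter | default | why |
|---|---|---|
| learning rate | 0.01 | stable on min–max-scaled inputs with MSE |
| batch size | 16 | small-cohort regime; batches of 1 are skipped (batch statistics undefined) |
| dropout | 0.2 | light regularization for n in the hundreds |
| batch-norm momentum | 0.9 | standard running-statistics smoothing |
| weight init | U(−1/√fan_in, 1/√fan_in) | fan-in scaling keeps early activations O(1) |

Regression targets are standardized internally (train mean/SD) and
predictions mapped back, so the default learning rate is well-conditioned
regardless of the target's units. Training is bit-reproducible: one integer
seed drives initialization, batch shuffling and dropout, and the package
never touches the caller's RNG state. Inference disables dropout and uses
the running batch-norm statistics, so prediction is deterministic. A
non-finite training loss aborts with a diagnostic rather than propagating
NaNs.

## The genetic search

Chromosomes are binary masks of length 12 over the canonical feature order
(frontal block, right maxillary block, left maxillary block — fixed because
chromosome bits index features positionally). The GA uses tournament
selection (size 2), single-point crossover (probability 0.8), independent
per-bit mutation at rate 1/L, and one elite chromosome, so best-so-far
fitness is non-decreasing. All-zero masks are repaired by setting one random
bit rather than being assigned zero fitness, which would waste evaluations.
These operator settings are standard small-GA choices; the method itself
prescribes only binary chromosomes and DNN accuracy as fitness.

Fitness of a mask trains the network on the masked features for a reduced
epoch budget (`fitness_epochs`, default 30) with a single fixed,
mask-independent seed, and evaluates accuracy on an internal validation fold
(default 20%) carved once from the training partition. The test partition is
never touched during the search, so the final reported metrics are honest.
Fitness values are cached by mask; exact fitness ties are broken toward the
smaller mask (the usual parsimony convention in wrapper selection — without
it, features that neither help nor hurt drift along with the search). For
regression the fitness is `1/(1 + RMSE)`, since classification accuracy is
undefined for a continuous target. After the search the final network is
retrained at full epochs on the selected features.

## The synthetic cohort generator

The study's clinical measurements are private, so the package ships a seeded
generator used by every test. It emulates:

* a cohort of 240 subjects, 129 female / 111 male, ages uniform on [18, 52]
  (the age distribution of the original cohort is unpublished; uniform is the
  neutral choice),
* sex dimorphism as standardized mean shifts on the nine linear dimensions
  (default +0.7 SD, male − female — craniofacial dimorphism of moderate
  size),
* a mild negative age trend (default −0.1 SD per decade),
* bilateral correlation between right/left maxillary homologues through a
  shared latent factor (default ρ = 0.6),
* volumes derived from their own sinus's dimensions,
  `V = c·L·W·H·e^ε`, `ε ~ N(0, 0.08)`, `c = 0.4`, so that volume features
  are largely redundant given the dimensions — the kind of redundancy that
  makes wrapper feature selection meaningful.

Baseline magnitudes (maxillary length ≈ 38 mm, volume ≈ 15,000 mm³,
frontal sinus ≈ 13 × 48 × 25 mm) are plausible adult values chosen to keep
CSVs readable; they claim nothing about the original data's distributions.
What the generator does **not** emulate: measurement error structure,
non-Gaussian shape variation, missing data, pathology-driven exclusions, or
any real covariance beyond the bilateral factor and volume coupling. Tests
passing on these cohorts therefore validate the pipeline's mechanics and its
statistical behaviour under a known model, not clinical performance.

`planted_relevance_cohort()` is the selection benchmark: a chosen subset of
features carries a standardized sex effect (default 2 SD) and the rest are
independent pure noise; all twelve features are generated independently so
ground-truth relevance is unambiguous, and the generating mask travels with
the data.

## Baselines

Logistic regression (binary or multinomial), random forest and a 150-100-50
ReLU multilayer perceptron run through the identical preprocessing and
evaluation path, always on the full 12-feature set. In the regression
scenario the "logistic regression" slot is ordinary least squares — the
published naming for a continuous outcome is nonstandard, and OLS is the
model actually meant. The random forest and (multinomial) logistic models
come from the standard library implementations; the MLP reuses the package's
own dense-network trainer with plain ReLU layers, since no multi-hidden-layer
perceptron is available in the dependency set. Hyperparameters beyond the
printed ones default to the library defaults and are recorded in the
comparison output.

## Evaluation

Classification reports are per-class one-vs-rest precision, recall and F1
plus overall accuracy, exactly as per-class tables are usually published —
no macro/micro averaging by default (available behind a flag). Ratios with
zero denominators are reported as 0 with a flag instead of NaN so reports
always serialize. Regression reports RMSE and R² (coefficient of
determination about the truth mean; constant truth flags R² as undefined and
reports 0).

## Numerical and design choices

* Softmax is always computed with per-row max subtraction; `softmax(x + c) =
  softmax(x)` exactly.
* The split keeps at least one row per stratum on each side and errors on
  singleton strata; fractions outside (0, 1) are rejected.
* Argmax ties decode to the lowest class index, deterministically.
* The published group sizes (39/70/90/40 before SMOTE, 90 per group after)
  are reproduced exactly by construction in the test suite; the published
  train/test counts per group are not reproducible from the stated 80/20
  protocol and are not emulated.
* Every run returns a manifest (task, configs, seeds, input checksum) from
  which `replay_run()` reproduces the reports bit-for-bit.

## Problem sizes used by the test and acceptance suites

Full GA runs at the method's defaults (population 20, 15 generations,
fitness epochs 30) train several hundred networks; the package's own
validation suites use deliberately smaller, documented configurations that
preserve the behaviour being checked:

* pipeline structure tests run a handful of epochs on cohorts of 100–150
  rows;
* the planted-relevance recovery runs use cohorts of 300–500 rows with
  population 10–12, 5–8 generations, 15 fitness epochs, a hotter fitness
  learning rate (0.05) and batch 64–96 — settings at which a fitness
  evaluation takes about a second;
* null-calibration and signal-recovery checks use cohorts of 400–1000 rows
  with the genetic search disabled (it is irrelevant to those properties).

## Known limitations

* MSE-on-one-hot with a softmax-bottlenecked trunk is the literal published
  design; it trains noticeably slower than cross-entropy with a softmax head
  (both alternatives are available via `train_config()`).
* The GA's fitness is a noisy estimate (one validation fold, one seed, few
  epochs); with strong signals the accuracy saturates and the ranking of
  near-optimal masks relies on the parsimony tie-break. More fundamentally,
  wrapper selection at cohort sizes in the hundreds cannot reliably
  distinguish features whose marginal accuracy contribution is below about
  one validation-fold standard error: with several strong, mutually redundant
  predictors, the last one or two of them are statistically invisible to any
  single held-out accuracy estimate, and no amount of extra search fixes this
  (a deeper search only gives lucky near-optimal masks more chances to win).
  Recovering a full redundant informative set reliably requires cohorts —
  and hence validation folds — several times larger.
* The simulator's Gaussian-plus-coupling model is a convenience, not a
  clinical claim.
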