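---
title: "Methods: ROI-based working-memory decoding and importance estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI-based working-memory decoding and importance estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roidecode)
```

## The analysis problem

The package decodes working-memory task conditions from ROI-averaged BOLD
time series. The experimental design it targets has four short-term-memory
tasks — two visuospatial (GLO: global processing, LOC: local processing) and
two verbal (SEM: semantic, PHO: phonological) — plus an eyes-open resting
state, recorded at TR = 1.8 s and averaged into 116 AAL-atlas regions. Each
of the 60 trials per session contains an encoding event (memorize a stimulus
set) and a retrieval event (recognize a probe), so the signal of interest is
event-locked and phase-specific.

Decoding proceeds in five stages, each an exported module surface:

1. **Segmentation** (`extract_phase_segments()`, `concatenate_segments()`,
   `build_rest_series()`): onset-locked windows per event, concatenated into
   one per-phase series per session.
2. **Problem assembly** (`problem_spec()`, `assemble_problem()`,
   `split_train_test()`): eight classification problems (ENC2…RET5), samples
   shaped 116 × 1 or 116 × 6, a stratified 90:10 split.
3. **Benchmark** (`run_benchmark()`, `weighted_f1()`): a dummy baseline plus
   ten classical and boosted classifiers, scored by support-weighted F1.
4. **Neural models** (`build_cnn()`, `build_resnet()`, `train_model()`): a
   1D CNN over 6-TR sequences and CIFAR-style residual networks.
5. **Importance** (`prune_importance()`, `perturbation_importance()`): a
   correlation-aware iterative-pruning score for tree ensembles, and a
   model-agnostic subset-zeroing prediction-flip score.

A synthetic generator (`generator_config()`, `generate_study()`) emulates
the study's data structure with known ground truth, so every stage is
validated end-to-end by parameter recovery rather than by eyeballing.

## Segment-length schedule

Event segments are nominally 10 s long, i.e. 6–7 TRs at TR = 1.8 s, and 60
of them are stated to concatenate to exactly 400 TRs. Those three numbers
cannot all hold simultaneously (10 s = 5.56 TR; the 6–7-TR range averages
20/3 per segment). We adopt a deterministic repeating schedule of
(7, 7, 6) TRs over trial index: 20 × (7 + 7 + 6) = 400, reproducing the
400-TR total exactly and keeping extraction reproducible. Segments start at
the TR containing the stimulus onset (`floor(onset / tr_seconds)`, 0-based)
and intentionally overrun the nominal event duration into the
distractor/inter-trial interval; no truncation at event offset is attempted.
Rest sessions have no events, so a contiguous 400-TR window is chosen
uniformly at random, cut into consecutive segments with the same schedule,
and the segment order is shuffled before concatenation.

## The synthetic generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is checked.

* **Noise.** Each ROI is an independent stationary Gaussian AR(1) process
  with unit marginal variance and lag-1 autocorrelation φ = 0.4 — a
  realistic effective autocorrelation for band-passed, nuisance-regressed
  BOLD at this TR. Rest sessions are pure noise with the same marginal
  variance as task baselines.
* **Activation.** Informative ROIs for a given (task, phase) receive an
  additive shift of `effect_size × temporal_profile` during each event's
  segment window. The default profile is a 6-point linear ramp
  (1/6 … 1, recycled at its last value for 7-TR segments); the default
  `effect_size` is 0.8 in units of the noise SD. A ramp rather than a full
  hemodynamic convolution is deliberate: the pipeline starts *after* voxel
  preprocessing and filtering, and a ramp gives 6-TR temporal models an
  exploitable within-segment signature while single-TR models see a
  position-dependent, partially diluted shift.
* **Informative sets.** By default, 8 ROIs per task and phase with 4 shared
  between the two visuospatial tasks and 4 between the two verbal tasks, on
  disjoint encoding/retrieval blocks. This keeps the 2-class groupings
  learnable while leaving task-specific structure for the 4/5-class
  problems. Note the consequence for recovery tests: for a merged 2-class
  contrast, only the *shared* ROIs are informative in every sample of their
  class; task-specific ROIs activate in half of their class's samples and a
  well-fitted classifier need not rely on them.
* **Correlated pairs.** `inject_duplicates()` rewrites a target row as a
  source row plus independent Gaussian noise, producing the
  highly-correlated, equally-informative feature pairs that plain
  split-count importance mishandles. For unit-variance sources the
  population correlation is `1/sqrt(1 + sd^2)` (≈ 0.995 at sd 0.1).
* **Session layout.** Trials repeat every 12 TRs (21.6 s): encoding onset at
  trial start (duration 1.5 s, the middle of the 1.2–1.8 s design range),
  retrieval onset 9 s later (duration 2 s), consistent with a
  distractor-then-probe trial and an ≈ 8.4 s inter-trial interval. With a
  5-TR tail a 60-trial session is 725 TRs, matching the scale of the
  reported 709–736 task volumes. Rest sessions default to 450 TRs so the
  400-TR rest-window procedure always applies.
* **Sessions are i.i.d. given the task.** The design does not state an
  inter-subject variance structure, so the generator treats sessions as
  exchangeable; per-session seeds derive deterministically from the study
  seed.

What the generator does **not** emulate: hemodynamic response shapes and
undershoots, physiological (cardiac/respiratory) noise, spatially smooth
inter-ROI noise correlations, subject-level random effects, motion
artifacts. Passing recovery tests therefore demonstrates algorithmic
correctness under the stated statistical structure, not performance on real
BOLD data.

## Evaluation: support-weighted F1

Per class *i*: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic
mean F1ᵢ, and weights Wᵢ = number of true samples of class *i*. The reported
score is `sum(Wᵢ·F1ᵢ)/sum(Wᵢ)` — the support-weighted average of per-class
F1, implemented exactly as this formula (true micro-averaging would collapse
to accuracy; the formula is the authoritative definition here). Zero-division
conventions: a class never predicted has precision 0 and hence F1 0; classes
absent from the truth carry zero weight. These conventions make degenerate
predictors scoreable.

For a baseline that samples predictions from the empirical class prior
independently of the features, expected precision, recall and F1 all equal
the class proportion pᵢ, so the expected weighted F1 is `sum(pᵢ²)`
(`expected_dummy_f1()`). On finite test sets the simulated mean sits
slightly below this because per-class F1 is a concave ratio of binomial
counts — the package's acceptance script reproduces the printed baseline
values by simulation, at the printed sample sizes, rather than quoting the
analytic limit.

## Benchmark roster and gradient-boosting tuning

The eleven `classifier_spec()` entries map onto established estimators:
glmnet (ridge), nnet::multinom (logistic regression), e1071 (linear SVM,
Gaussian naive Bayes), MASS (LDA/QDA), rpart (decision tree), ranger
(random forest), and xgboost for both gradient-boosting entries
(`tree_method = "hist"`, `grow_policy = "lossguide"`, `max_leaves = 31` —
the leaf-wise growth policy of LightGBM-style boosting). The linear SVM is
fitted by an exact QP solver rather than stochastic gradient descent; SGD
is a fitting strategy, not a different estimator, and desk-scale problems
do not need it. Hyperparameters of the untuned classifiers are the backing
packages' defaults, logged in each spec.

Tuning searches the six boosting hyperparameters within fixed bounds
(L1/L2 in [1e-8, 10] sampled log-uniformly; leaves in [2, 128]; feature and
bagging fractions in [0.1, 1.0]; bagging frequency in [1, 7]) by seeded
uniform random search with the default configuration always included, so
the winner never scores below the default on the validation split. A
Bayesian/TPE optimizer would need a dependency the package does not carry;
with ~100 trials in a 6-dimensional box, random search is a standard,
reproducible substitute. Since xgboost has no every-k-rounds bagging
schedule, a sampled bagging frequency > 0 enables per-tree row subsampling
at the sampled fraction. The tuning validation set is a stratified 80:20
sub-split of the training partition; the test set is never touched.

The default train/test split is sample-level and stratified. Because t = 1
samples are consecutive TRs of a concatenated series, sample-level splitting
leaks temporal autocorrelation across the partition — decoded accuracy is
optimistic in absolute terms. A grouped split (`by_session = TRUE`) is
provided for leakage-free evaluation; the default mirrors the original
protocol.

## Neural models

**1D CNN** (t = 6 only): two 1D convolutions, max pooling, a third
convolution, then a dropout + linear layer and softmax; every kernel has
length 3 and slides along time with the ROIs as input channels, so each
filter can combine any subset of regions at adjacent time points. Default
channel widths are 64/64/128; the test suite uses 16/16/32, which trains in
seconds on one CPU and is already sufficient for the planted signals.

**ResNet**: the input is a single-channel 116 × t image with ROIs in atlas
order (left/right homologs adjacent), an input 3×3 convolution with batch
norm, three stages of k residual blocks (depth 6k + 2 for sizes 14/20/32/56),
stage widths 16/32/64 by default, stride-2 downsampling entering stages 2
and 3, global average pooling, dropout, and a linear logit layer. Every
block has two 3×3 convolutions with a batch normalization after each and an
identity shortcut, replaced by a 1×1 strided convolution where the shape
changes. For t = 1 inputs the 3×3 kernels run over a zero-padded
single-column image; this layout is a reconstruction, flagged as such, since
the exact published input arrangement is not stated.

All layers (im2col-based 1D/2D convolution, batch norm, pooling, dropout,
dense) carry hand-written forward and backward passes in base R matrix code;
the gradients are verified against central finite differences to ~1e-9
relative error in the test suite. Training uses Adam (β₁ = 0.9, β₂ = 0.999),
minibatches (default 32), weight decay where configured, a
reduce-on-plateau scheduler (factor 0.1, patience 3 — the scheduler is
named in the protocol, its parameters are this package's defaults), and
early stopping when validation loss fails to improve for 5 consecutive
epochs (cap 100), restoring the best-validation weights (including batch-norm
running statistics). The stopping rule is factored into `early_stop_epoch()`
so it can be tested on scripted loss sequences. The validation set for
early stopping is a stratified 80:20 sub-split of the training partition.

## Importance, algorithm 1: iterative pruning

Split-count importance for a tree ensemble counts how often each feature
splits a node. It is blind to correlations: of two equally informative,
highly correlated ROIs, one can absorb nearly all splits while its twin
scores near zero — removing the first would hand its importance to the
second. The pruning procedure corrects this: repeatedly (i) fit the
classifier on the remaining ROIs, (ii) compute split counts, (iii) z-score
them across the remaining ROIs to correct for the shrinking feature count,
(iv) append each ROI's z-score to its buffer, and (v) remove the
highest-scoring ROI. An ROI's final score is the median of its buffer over
the steps in which it was present.

Numerical conventions: argmax ties break toward the lowest ROI index
(determinism); a zero-variance score vector (all counts equal) z-scores to
all zeros; the loop stops when one ROI survives — the survivor is appended
to the removal order with its last buffered value, since z-scoring a
singleton is undefined. The written pseudocode aggregates buffers by median
while the accompanying prose says averaged; the median is the default here
and the mean is available via `aggregate = "mean"`. Scores at each step come
from freshly retrained models with the factory's fixed configuration —
untuned gradient boosting by default, matching the validation choice of the
original procedure. The per-step matrix of importance changes
(`delta_matrix()`) makes the compensation visible: removing one member of a
correlated pair produces a positive delta on its twin.

A property worth knowing before interpreting final scores: a twin that is
shadowed for *many* steps (because other, stronger features are removed
first) accumulates a buffer dominated by its shadowed entries, and its
median stays low. The correction is therefore most faithful when the
correlated pair sits near the top of the importance ranking — which is the
regime the method was designed for. The package's recovery test plants a
strongly informative duplicated pair (d = 2.0 , correlation ≈ 0.995) among
noise ROIs; both members then outrank every noise ROI in 10/10 seeds. At
d = 1.0 a single planted direction is too sparse for split counts in
31-leaf boosted trees (most splits chase noise), and the same end-to-end
run with the reference LightGBM implementation shows the identical failure —
the limitation belongs to split-count importance, not to this
implementation.

## Importance, algorithm 2: subset-zeroing perturbation

For any fitted model: per iteration, sample one uniform subset of k ROIs,
zero those rows in every validation batch (acting on the model's input
representation), and record for each batch the fraction of hard-label
predictions that flip relative to the unperturbed batch; the score lands in
the buffer of every ROI in the subset, and an ROI's importance is its buffer
mean. Defaults follow the reference run: N = 10,000 iterations, k = 12 of
116 ROIs; the batch size (64) is unstated in the source and configurable.
Scores are kept as fractions in [0, 1]; z-scoring is applied only when
comparing against pruning scores in plots, not stored. Hard-label
comparison is used rather than probability distances (reported not to
change results materially). The sampled subset is drawn once per iteration
and shared by all batches of that iteration, so one forward pass over the
perturbed validation set scores every batch. On any ≤ 8-ROI problem the
procedure is checked against exhaustive enumeration of all C(n, k) subsets.

## Problem sizes used in the test suite

The suite regenerates all data in code: 116-ROI single- or multi-session
studies for end-to-end checks (≈ 2,000 single-TR samples per problem),
compact 10–24-ROI synthetic atlases for algorithmic properties, 200-seed
dummy-baseline simulations at the printed sample sizes (2,000 / 1,600), the
pruning recovery at 20 ROIs × 2,000 samples × 10 seeds, perturbation
recovery at N = 2,000 iterations × 5 seeds, and CNN training with 16/16/32
channels over ≤ 100 epochs × 5 seeds. These sizes are the package's
validation choices: large enough for stable statistics, small enough to
rerun routinely.

## Known limitations

* Real-data F1 levels are not reproducible from synthetic inputs; only the
  baseline row, structural totals and algorithmic properties are.
* The generator's independence assumptions (across ROIs except explicit
  duplicates, across sessions) understate real BOLD dependence; recovery
  precision on real data will be lower.
* Split-count importance — even pruned — reflects what the *model* uses,
  not all information present; ROIs redundant with stronger ones may
  legitimately never surface (see the shadowing note above).
* The sample-level default split inherits the original protocol's temporal
  leakage; use the session-wise split for conservative estimates.
* ResNet-56 is constructible and gradient-checked but not exercised in
  routine tests; CPU training at full widths is possible but slow.
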