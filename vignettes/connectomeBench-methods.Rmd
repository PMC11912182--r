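---
title: "Methods: standardized benchmarking of connectome classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized benchmarking of connectome classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectomeBench)
```

## The problem this package addresses

Case/control classifiers for neurodevelopmental conditions are usually
trained on multi-site resting-state functional connectivity and structural
morphometry, and published accuracies vary far more than the models
plausibly differ. Much of that variation traces to the experimental frame:
which participants are included, how features are selected, and whether the
tuning and test data are truly disjoint. `connectomeBench` fixes the frame
so that five standard architectures — a Gaussian-kernel SVM, a fully
connected network (FCN), an autoencoder-classifier (AE-FCN), a Chebyshev
graph convolutional network on a same-site population graph (GCN), and an
edge-variational graph network with a trainable pairwise association
encoder (EV-GCN) — can be compared like-for-like, and so that their
saliency maps can be compared for stability rather than only accuracy.

Because real multi-site cohorts cannot ship with a package, the unit of
experimentation here is a synthetic cohort with planted ground truth. The
generator is first-class, tested code: every downstream claim (accuracy,
leakage-freedom, saliency recall) is validated against effects the
generator provably planted.

## The synthetic cohort generator

`generateCohort()` emulates a 20-site case/control cohort whose per-site
composition, mean ages and sex ratios follow the package's built-in
reference table (`abideSiteTable()`: 870 participants, 403 cases, 20
sites; `scale < 1` shrinks every site x label cell, keeping at least one
participant per non-empty cell so the stratification structure survives
desk-scale work).

Connectivity is generated in Fisher-z space: each edge has a cohort-level
backbone value (SD 0.25), plus a per-site offset drawn once per site
(`site_shift_sd`, default 0.15), plus participant noise (`noise_sd`,
default 0.3), and planted edges receive a between-class shift of
`effect_size_d` within-class standard deviations (where the within-class
SD combines the site and noise scales). The z-values map through `tanh`,
so matrices are symmetric, unit-diagonal and bounded in (-1, 1); because
the backbone keeps z-values in the near-linear range of `tanh`, the
realized standardized mean difference on planted edges stays close to the
dial (the generator's tests check both the direction and the approximate
magnitude). Structural features follow the same additive scheme without
the `tanh` map. Optionally, `generateTimeseries()` draws Gaussian BOLD-like
series whose empirical correlation converges to a target matrix, so the
Pearson-correlation step of the pipeline can be exercised from raw series.

What the generator deliberately does *not* emulate: hemodynamics, temporal
autocorrelation, scanner-specific artifacts, heavy-tailed motion effects,
or correlated (non-independent) site effects across features. Passing
recovery tests therefore demonstrates that the pipeline is correct and
leakage-free under the stated statistical structure, not that any
architecture will reach a particular accuracy on real data.

Quality-control phenotypes (motion-outlier count/percentage, anatomical
rating) are drawn independently of the class label by default; a
`qc_label_leak` knob exists for ablations that study what happens when QC
correlates with diagnosis.

## Feature pipeline

For each participant the upper triangle of the connectivity matrix is
flattened in a fixed row-major (i < j) order (19,900 edges for 200 ROIs),
and structural tables are flattened region-by-region (68 cortical regions
x 9 measures + 115 noncortical regions x 7 measures = 1417 features at the
reference atlas sizes). Standardization removes the mean and scales to
unit variance using the population (1/n) convention — stated so tests can
be exact — with zero-variance columns floored at scale 1e-12 (they
standardize to exactly 0 instead of propagating NaN).

Feature selection is recursive feature elimination under a closed-form
ridge classifier (unit penalty; selection is rank-based, so the penalty
scale matters little). By default 10% of the surviving features are
dropped per iteration; `step = 1` gives the classical one-at-a-time
variant. The implementation keeps the training Gram matrix and downdates
it as columns are eliminated, which makes the ranking essentially linear
in the feature count. Reference selections are 4000 connectivity and 800
structural features; desk-scale experiments use proportionally smaller
values.

Both the standardizer and the RFE ranking are re-fit inside every
cross-validation (and nested cross-validation) training split — 5 times
for plain CV, 25 times for nested CV. The six non-imaging measures (age,
sex, FIQ, motion-outlier count and percentage, anatomical rate) are
appended unselected; we standardize them together with the imaging blocks
(the uniform treatment is the simpler contract; a config flag would be
trivial but the package takes one documented position).

## The five architectures

All classifiers satisfy one contract: `classScores()` returns
probability-like rows summing to one, and the differentiable
architectures expose `inputGradient()`, the gradient of the requested
class's *pre-softmax* score with respect to the input features (softmax
saturation suppresses gradients, so saliency is computed on logits).

* **SVM** — RBF kernel with the "scale" bandwidth (`1/(p Var(X))`), C
  tuned on the validation split. Scores are a logistic squashing of the
  signed decision values calibrated on training data, with the slope
  capped so perfectly separated fits do not emit hard 0/1 scores.
* **FCN** — N-500-30-2 with dropout 0.5 after both hidden layers,
  rectifier hidden activations and a linear output before softmax.
* **AE-FCN** — encoder N-300-150, decoder 150-300-N, classifier head
  300-16-2. The total loss is reconstruction MSE plus cross-entropy with
  unit weights. The head consumes the *reconstruction* (dimension N); the
  width sequence makes this the consistent reading of the reference
  description, whose caption also asserts two equal-width layers that its
  explicit numbers (150 vs 16) contradict — we follow the explicit
  widths, and a `head = "bottleneck"` switch exposes the alternative.
* **GCN** — transductive, three Chebyshev layers N-128-128-2 of order
  K = 3 on the binary same-site population graph, dropout 0.3 between
  layers. The loss is masked to training nodes; validation-node accuracy
  selects the checkpoint; test labels never touch either.
* **EV-GCN** — a pairwise association encoder (PAE) embeds each
  subject's one-hot sex and site encoding linearly and scores a pair by a
  logistic affine function of `[|h_i - h_j|, h_i * h_j]` — pair-symmetric
  and differentiable, our committed reading of the "adaptive population
  graph" idea, since the reference defers the internal form to its
  citation. The dense learned graph (the full matrix, not only an upper
  triangle) passes through edge dropout (rate 0.3, training only),
  symmetric normalization, and four 16-channel Chebyshev layers whose
  outputs are concatenated (width 64 = 16 x 4) into a 256-unit MLP.
  PAE parameters receive gradients through the graph normalization.

Optimization is full-batch Adam (learning rate 1e-3; 5e-3 for the graph
models; weight decay 5e-4) — the defaults of the graph-convolution
literature the architectures come from. The "number of iterations"
hyperparameter is selected on the validation set over a checkpoint grid
(every 10 epochs up to 300 by default; the desk-scale experiments use a
100-epoch budget). Training is bit-deterministic given the spec seed.

### Numerical conventions for the graph machinery

The Chebyshev basis needs a rescaled Laplacian `L~ = 2L/lambda_max - I`.
For the fixed site graph, `lambda_max` is computed exactly by dense
eigendecomposition up to n = 2000 (power iteration with tolerance 1e-6
beyond, though cohorts here are far smaller). Isolated nodes get a unit
self-connection in the normalized adjacency, so an empty graph yields
`L~ = -I` and the convolution degenerates to a per-node linear map — the
sensible continuum limit, verified in tests. For the *learned* EV-GCN
graph we take `lambda_max = 2` (the standard Chebyshev-net convention);
this keeps `L~ = -D^{-1/2} W D^{-1/2}` differentiable in the PAE
parameters without differentiating an eigenvalue. Because the PAE input
is one-hot sex/site, subjects fall into at most `2 x n_sites` distinct
encodings; edge weights are computed on unique encoding pairs and
expanded through the group-membership matrix, which also pools gradients
exactly.

## Evaluation pipelines

`makeStratifiedFolds()` deals the members of every (site, label) cell,
shuffled by seed, round-robin starting at the currently smallest fold;
this guarantees deterministically that each cell splits across the k
folds within one member. The fold plan is fixed once per experiment and
shared by all architectures and feature modes, so paired comparisons
across models are valid.

`runCV()` rotates test/validation/training groups so every sample is
scored exactly once by a model that never saw it; hyperparameters (C or
iteration count) are chosen on the validation group per fold. `runNestedCV()`
re-splits the four non-test groups into five inner folds with the same
stratification; the hyperparameter is chosen by the best *average* inner
validation accuracy per outer fold, and the five inner models retrained
at that value vote on the outer test set (25 models per architecture;
tests audit that no outer-test sample enters any inner split). Networks
are retrained at the selected iteration count rather than snapshotting
every checkpoint of every inner model; training is seed-deterministic, so
the retrained model is the model that produced the selected grid entry.

The chance control deserves a note. In a multi-site cohort with per-site
feature offsets, a *global* label permutation leaves randomly uneven
per-site label rates, and a site-aware classifier can learn them and beat
0.5 on the permuted cohort without any leakage (the site-majority oracle
on such a permutation of the desk-scale cohort sits near 0.57). The
package's chance control (`nullPermutation()`) therefore uses a
restricted permutation in the exchangeability-block tradition: the label
multiset is re-apportioned across sites proportionally to site size
(largest remainder, exact in the class totals) and shuffled within site,
which removes the site-composition association and makes pooled accuracy
on the permuted cohort estimate chance plus the global class imbalance.

Metrics are accuracy and AUC (rank formula; ties count one half).
`pairedTTest()` implements a dependent-samples t-test on per-fold metric
vectors — the natural reading of a "two-sample paired" comparison, which
is self-contradictory if taken literally — with `p = 1` by convention for
identical vectors. `chiSquaredBest()` compares two models' 2 x 2
correct/incorrect contingency without continuity correction, so the
statistic equals the textbook closed form.

Ensembles: `maxVote()` (modal label over same-architecture inner models;
even-split ties break by mean autism score and fall back to TD on exact
score ties — the reference design only ever uses odd voter counts) and
`emmaVote()` (majority over the five architectures' pooled CV
predictions; five voters and two classes admit no ties).

## SmoothGrad saliency and the stability statistic

`smoothGrad()` perturbs a participant's input with 10 elementwise
Gaussian draws whose SD is 10% of the per-feature training range (the
SmoothGrad literature's convention; the range is stored on every trained
model), averages the signed gradients, and takes absolute values
("abs-of-mean"; a "mean-of-abs" flag exists). For a linear scorer this
returns exactly the absolute weights — a test identity. The SVM exposes
no input gradient and is rejected explicitly. For the graph models the
gradient is taken with respect to the node's own feature row with the
population graph held fixed.

For stability, each participant gets five saliency maps from the five
inner models of its outer fold; maps from models with different RFE
selections are embedded into the full feature space (unselected features
carry zero saliency, so selection instability correctly depresses the
statistic). The per-feature SNR is mean/std (sample std, n-1); a
participant's value is the mean over features, with zero-std features
floored at 1e-12 and excluded from the average but counted in a flag —
keeping histograms finite without inventing infinities. The nested run is
repeated (3 times in the full design) with fresh initializations and each
participant's SNR is averaged over repeats before pooling into
histograms; averaging per participant first is our resolution of an
ambiguity in the reference description, and it keeps the histogram unit
"participant". Saliency aggregation to regions (`nodalStrength()`) sums
each connection's saliency into both incident regions (mass is conserved:
strengths total twice the edge saliency) and is z-scored for comparison.

## Problem sizes and budgets

The test suite and the acceptance script exercise the full pipeline on a
scaled cohort the package adopts as its standard desk scale: the 20-site
table at 0.69 scale (580 participants, 270 cases), 64 ROIs (2016 edges),
203 structural features, 50 planted edges and 20 planted structural
features at effect size 1.5, with 500/100 features kept by RFE and a
100-epoch training grid. These sizes were chosen so a complete recovery
study — five architectures under cross-validation, a label-permuted
chance control, five seeds of nested max-voting, and a saliency-recall
experiment — runs in minutes on one CPU while keeping every per-site cell
populated. Unit tests use still smaller cohorts (16 ROIs, ~47
participants).

## Known limitations

* The site effect is additive and feature-independent; real scanner
  effects are correlated and partly multiplicative. Harmonization methods
  are out of scope.
* The reference accuracies reported for real multi-site cohorts (around
  70%) are not reproducible from synthetic data and are not targets of
  this package; on planted cohorts the pipelines sit near ceiling by
  design.
* Graph architectures are transductive: they require the full population
  graph at training time and cannot score genuinely unseen cohorts
  without retraining.
* The AE-FCN head and PAE internals follow documented committed readings
  (above) where the reference descriptions are ambiguous; both admit
  configuration switches rather than silent alternatives.
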