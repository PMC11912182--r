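# connectomeBench

Standardized benchmarking and interpretation of machine-learning
classifiers on multi-site case/control connectome cohorts.

Published case/control classifiers for autism trained on resting-state
functional connectivity and structural morphometry report accuracies
anywhere between 60% and 85%. Most of that spread comes from the
experimental frame — inclusion criteria, feature selection hygiene, and
whether tuning data really stayed out of the test set — rather than from
the model family. `connectomeBench` pins the frame down so that model
families can be compared like-for-like, and so the comparison itself can
be validated on synthetic cohorts with *known* ground truth:

* **Synthetic multi-site cohorts** (`generateCohort()`): a 20-site
  case/control cohort generator with per-site composition matching a
  reference 870-participant table, additive per-site offsets, and a
  configurable number of planted class-discriminative connectivity edges
  and structural features at a chosen standardized effect size *d*.
  Connectivity effects are applied in Fisher-z space and mapped through
  `tanh`, so matrices stay valid correlation matrices.
* **Leakage-free feature pipeline**: upper-triangle vectorization of the
  n x n connectivity matrix (`vectorizeUpper()`, n(n-1)/2 edges in fixed
  row-major order), structural flattening (68 x 9 + 115 x 7 = 1417
  features at reference atlas sizes), train-only standardization
  (`fitStandardizer()`), and recursive feature elimination under a ridge
  classifier (`rfeRank()`), re-fit inside every training split.
* **Five classifiers** behind one score/gradient contract
  (`classScores()`, `inputGradient()`): RBF-kernel SVM, a fully
  connected network (N-500-30-2, dropout 0.5), an autoencoder-classifier
  (encoder N-300-150, joint MSE + cross-entropy loss), a Chebyshev graph
  convolutional network (K = 3, N-128-128-2) on the binary same-site
  population graph, and an edge-variational graph network whose dense
  population graph is produced by a trainable pairwise association
  encoder from sex and site encodings (four 16-channel layers fused into
  a 64-256-2 MLP, edge dropout 0.3).
* **Two evaluation pipelines**: site x label stratified 5-fold
  cross-validation with a dedicated validation fold for hyperparameter
  tuning (`runCV()`), and 5 x 5 nested cross-validation training 25
  models per architecture for max-voting ensembles (`runNestedCV()`),
  plus EMMA majority voting across the five architectures
  (`emmaVote()`), paired t-tests and chi-squared model comparisons.
* **SmoothGrad stability analysis**: per-participant saliency maps
  averaged over 10 noise-perturbed inputs (`smoothGrad()`), the
  signal-to-noise stability statistic across the five inner models of a
  nested fold (`participantSNR()`, SNR = feature-wise mean/std), repeat
  pooling and histograms (`saliencyStability()`), nodal saliency
  strength and TP/TN/FP/FN feature summaries.

## Worked example

```r
library(connectomeBench)

# A desk-scale synthetic cohort: the 20-site table at 5% scale (47
# participants), 16 ROIs (120 edges), 57 structural features, with 10
# planted edges and 5 planted structural features at d = 1.5.
cfg <- generationConfig(n_rois = 16, site_table = abideSiteTable(0.05),
                        n_informative_edges = 10, n_informative_struct = 5,
                        n_cortical = 4, n_noncortical = 3,
                        effect_size_d = 1.5, seed = 7)
cohort <- generateCohort(cfg)
cohort
#> Cohort with 47 participants from 20 sites
#>   autism: 23  td: 24
#>   fc matrices: 16 x 16
#>   structural features: 57
#>   synthetic ground truth: 10 planted edges, 5 planted structural

# One fixed stratified fold plan, shared by every model.
plan <- makeStratifiedFolds(phenotypes(cohort)$label,
                            phenotypes(cohort)$site, k = 5, seed = 3)

# Five-fold CV of the SVM on combined structural + connectivity features,
# keeping 30 edges and 15 structural features by ridge-RFE per fold.
res <- runCV("svm", "s+f", plan, cohort, k_fmri = 30, k_smri = 15,
             seed = 11)
res
#> CVResult [svm, features=s+f]: pooled accuracy 0.979, AUC 1.000
```

The pooled accuracy is computed from each participant's prediction made
when their fold was the test fold — every participant is scored exactly
once by a model that never saw them. On this planted cohort (d = 1.5) the
classifier sits near ceiling; with `effect_size_d = 0` the same pipeline
returns chance-level accuracy, which is precisely what the leakage audits
in the test suite assert.

The saliency stability statistic, on its hand-checkable example — five
saliency maps that scale two features linearly (1..5 and 2..10):

```r
participantSNR(cbind(1:5, 2 * (1:5)))$average
#> [1] 1.897367
```

`recoveryExperiment()` chains the whole study (all five architectures,
chance control, nested max-voting over five seeds, FCN saliency recall of
the planted edges) at the package's standard desk scale of 580
participants and 2016 edges.

A thin command-line driver is installed at
`inst/scripts/cbench.R` (stages `simulate | prepare | evaluate | nested |
ensemble | interpret | stability | report`, configured by a YAML file);
each stage writes delimited-text artifacts and `report` summarizes them
without retraining.

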