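---
title: "Methods: network-based individual differences in memory and metacognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based individual differences in memory and metacognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamemnet)
```

## The problem and the data model

Studies of the associative deficit in aging compare younger and older
adults on recognition of single items versus studied pairings, usually by
averaging within age groups. Averaging hides heterogeneity: if some older
adults monitor their memory confidently and accurately while others do the
opposite, the group means on metacognitive measures can look
age-equivalent even though no individual older adult is "average".
`metamemnet` implements a pipeline for surfacing such latent subgroups.

Each participant contributes 18 measures — a 9-measure grid crossed with
two test types (item, associate):

| measure       | scale  | meaning |
|---------------|--------|---------|
| `performance` | −1..1  | hit rate minus false-alarm rate |
| `mseq`        | 0..100 | memory self-efficacy (mean confidence over graded levels, "No" = 0) |
| `postdiction` | 0..100 | after-test estimate of how much was remembered |
| `pda`         | −1..1  | postdiction accuracy: postdiction/100 − proportion correct |
| `strategy`    | 0..100 | perceived strategy success |
| `difficulty`, `effort`, `fatigue`, `stamina` | 1..5 | task-experience ratings |

For an equal old/new (intact/recombined) test, proportion correct equals
`(1 + performance)/2`, because (hits + correct rejections)/total =
(n + hits − FA)/2n; `postdiction_accuracy()` uses exactly this identity,
so negative values mean underestimation of one's own performance.
Canonical column order is test-type major (9 item columns, then 9
associate columns) so that weight indices and ablation subsets are stable;
`read_cohort()` maps arbitrary CSV headers onto this grid through a
dialect configuration, since deposited data sets rarely share a naming
scheme.

## The classifier network

The core model is deliberately small: p inputs (18, or 9 under ablation),
h = 2 hidden units, one output, fully connected, every unit squashing
its weighted input plus bias through the bipolar logistic
$f(x) = \frac{2}{1+e^{-x}} - 1$, which maps onto (−1, 1) and is
algebraically $\tanh(x/2)$ (the form used internally; the derivative is
$(1 - f(x)^2)/2$). Targets are −1 for younger and +1 for older adults.
Inputs are the z-scored measures (sample SD, denominator n − 1).

Training is plain full-batch gradient descent on the summed squared error
$E = \sum_i (t_i - o_i)^2$ — iterative error correction with a fixed
learning rate and no momentum, minibatching or regularization. Tunable
parameters, with defaults:

* `init_range` = 0.005: weights and biases start uniform in
  [−0.005, 0.005). The tiny range makes the initial network nearly linear
  and the error surface entry point reproducible; endpoint handling of the
  half-open interval is immaterial at this scale.
* `learning_rate` = 0.05: small enough that the full-batch error history
  is non-increasing on every problem in the test suite (asserted to 1e-12
  slack); larger rates can overshoot once outputs saturate.
* `max_epochs` = 20000 and `convergence_tol` = 1e-10 on the per-epoch
  change in E. Because targets ±1 are asymptotic for the activation, E
  never reaches zero; the run stops on error-change convergence or the
  epoch cap, whichever comes first. Simulation studies in the test suite
  cap LOOCV fold training at 2000 epochs: the *sign* of the output — all
  that classification and d′ use — stabilizes one to two orders of
  magnitude earlier than the last decimals of E, and the cap keeps the
  106-fold × many-replicate studies tractable on one CPU.

Gradients are analytic backpropagation, implemented in C++ for speed and
exposed to R (`nn_gradient()`) so the test suite can verify them against
central finite differences (relative error < 1e-5 over dozens of random
architectures). Classification is by output sign, with an exact zero — a
measure-zero event — resolved to "young" so the rule is total.

## Probing, clustering, and cluster statistics

`hidden_activations()` records the 2-D hidden representation of every
participant; this latent space, not the output, is the scientific object
of interest. `kmeans_latent()` clusters it with Lloyd's algorithm,
k-means++ seeding, 50 restarts (best within-cluster sum of squares wins),
per-iteration monotonicity assertions, and an explicit empty-cluster rule
(a centroid that loses all points is re-seeded to the farthest point from
its current centroid). k is fixed at 3 by default — the design this
package exists for — with no model-selection criterion implied; raw
activations are clustered, without rescaling, since both dimensions
already live in (−1, 1).

k-means labels are arbitrary, so `canonicalize_clusters()` fixes them:
cluster 1 is the cluster richest in younger adults; of the remaining two,
cluster 2 has the higher mean z-scored associate postdiction accuracy
(the confident-and-accurate older group), cluster 3 the other. Cluster
profiles report per-cluster means ± SE of the z-scored inputs (zero =
sample average), and `cluster_feature_anovas()` runs a one-way ANOVA per
variable across clusters with Bonferroni correction for 18 tests
(significance flag at raw p < .05/18 ≈ .0028) and partial η².

## Evaluation

`loocv()` implements leave-one-out cross-validation with strict
anti-leakage hygiene: within each of the n folds the feature subset is
selected, the n − 1 training rows are z-scored *on themselves*, the
held-out row is standardized with the training-fold statistics only, and
a fresh network is initialized with a fold seed derived from the base
seed plus a stable hash of the held-out participant's id — so results are
invariant to row order. Predictions aggregate to d′ with older adults as
the signal class. Because perfect rates occur at these sample sizes, 0
and 1 are corrected to 1/(2N) and 1 − 1/(2N) by default (log-linear
correction available). `ablation_compare()` runs the item-only and
associate-only LOOCVs under matched fold seeds, a paired design that
removes shared Monte-Carlo noise from the reported difference.

Normalization order under ablation: z-scores are recomputed on the 9
retained columns, which is numerically identical to slicing the 18-column
z-matrix (standardization is column-wise; a test asserts the
equivalence), so the declared order costs nothing and removes ambiguity.

## The univariate layer

`mixed_anova()` is the classical split-plot decomposition for 2 (Age) ×
3 (Stimulus) between-subjects factors and a 2-level within factor (Test
Type): between-subjects effects are tested against subjects-within-groups
error (df = N − 6), within-subjects effects against the
TestType-by-subjects error. Unequal cell sizes use the unweighted-means
solution (cell means weighted by the harmonic mean of cell sizes), the
classical split-plot treatment; on balanced designs it reduces exactly to
the textbook decomposition, where the test suite verifies it against
`stats::aov` with an `Error(subject/test)` stratum and checks that effect
and error SS sum to the total. Partial η² is
SS_effect / (SS_effect + SS_error-of-that-stratum).

Cohen's d uses the average-SD standardizer |m₁ − m₂| / ((s₁ + s₂)/2) by
default: the demographic-table worked examples in the test suite pin this
convention (the pooled-SD form, also available, fails to reproduce the
education effect size, 1.86 vs the printed 1.96). Pooled t tests are
callable from summary statistics so printed tables can be checked
directly. The post-hoc stimulus-type comparisons deliberately enter each
subject's item and associate scores as two independent observations —
statistically odd (it ignores the within-subject correlation), but it is
the convention implied by the degrees of freedom these comparisons are
reported with (e.g. t(142) for conditions of 36 + 36 subjects), and the
package replicates rather than silently repairs it.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts with known ground truth so every
downstream stage is testable. Defaults emulate the study design this
package models: 57 younger and 49 older adults; older adults split into
two latent clusters of 12 and 36, with the single remaining older adult
generated from the young-typical profile and one younger adult generated
from the older confident-cluster profile (these two crossovers reproduce
near-perfect but imperfect group separation). Each measure is
`base mean + base SD × (cluster offset + N(0, residual SD))`, clipped to
its legal range (clip counts are reported) and rounded to 6 decimals so
CSV round-trips are lossless. Base means and SDs average the two age
groups' published summary values per variable; the residual SD defaults
to 1 z-unit.

The offset pattern (`default_effect_pattern()`, magnitude 0.9 z) places
zero offsets on both recognition-performance columns — the latent
structure lives in metacognition, not accuracy — and perturbs nine
variables: cluster 2 is high on item/associate postdictions, strategies
and postdiction accuracies and on associate self-efficacy, low on
associate difficulty and item fatigue; cluster 3 mirrors it on every one
of those variables. Cluster 1 (young-typical) sits at baseline on the
postdiction/strategy/accuracy variables but shares cluster 2's side on
associate self-efficacy and associate difficulty, and is elevated on item
fatigue. This was a genuinely open design choice: the motivating study plots
but does not print its cluster profiles. We chose this layout over two
alternatives after simulating all three, because it is the only one that
reproduces the study's headline multivariate property — associate-task
measures carry more age information than item-task measures (the
young-typical cluster differs from the large older cluster by twice the
offset on the two shared associate variables, while item measures mainly
separate the small older cluster). Treating item fatigue instead as a
uniform young-versus-old cue (high young, low in both older clusters)
makes the *item* subset dominate out-of-sample classification, inverting
the phenomenon the generator exists to emulate; placing cluster 1 at zero
everywhere except fatigue weakens the associate advantage to a coin flip.
The adopted pattern yields mean LOOCV d′ near 0.9 (item) and 1.3 to 1.4
(associate) under default conditions.

What the generator does *not* emulate: residual correlations between
measures (variables are independent given the cluster — no covariance
information is available to calibrate them); the deterministic dependence
of postdiction accuracy on postdiction and performance (it is drawn as its
own variable); stimulus-condition effects (condition is uniform random
metadata); and item-level responses. Consequently, passing tests show the
pipeline recovers structure of this idealized form; they cannot show how
the method behaves under correlated measurement error, and the cluster
ANOVA effect sizes on synthetic data (partial η² roughly 0.2 to 0.6) are
much smaller than in the tightly separated empirical clusters of the
motivating study (0.88 to 0.96), because a full 1-z residual SD is generous.

## Pipeline, seeds, and problem sizes

`run_replication()` executes the declared stage order and persists every
intermediate artifact (cohort and truth CSVs, model JSON, hidden
activations, cluster and ANOVA tables, LOOCV report, univariate tables,
merged summary). One global seed fans out additively to fixed per-stage
offsets, so changing the clustering seed cannot alter the trained model;
a test asserts byte-identical artifacts across repeated runs.
`run_robustness()` repeats the pipeline across derived seeds and hidden
layer sizes (2 and 3) and reports how often the qualitative pattern —
a majority-young cluster plus two majority-old clusters with the
larger one outnumbering the smaller — recurs.

Simulation studies in the test suite use 20 replicate cohorts at the
default n = 106, 50 k-means restarts, default full-cohort training, and
2000-epoch LOOCV folds; the parameter-recovery study measures cluster
recovery by the adjusted Rand index between truth and canonical labels.

## Known limitations

* Recovery of the *two older subgroups* from hidden space is not
  guaranteed run to run: the network is trained only to separate young
  from old, and in a minority of runs the 2-D hidden representation
  spreads the large young group more than it separates the two older
  corners, so k-means splits the young cluster instead. Exact agreement
  between the Bonferroni-significant variable set and the generator's
  offset set then fails even though truth-cluster ANOVAs recover the set
  almost always. Training longer does not remove this; it is a property
  of the objective, faithfully reproduced rather than patched.
* d′ from 106 leave-one-out predictions carries binomial noise of roughly
  ±0.25; orderings between feature subsets hold in most but not all
  replicates at the default effect sizes.
* The unweighted-means ANOVA does not decompose the total SS additively
  on unbalanced data (no method does without choosing a weighting); SS
  conservation is asserted on balanced designs only.
* MSEQ validation enforces confidences in {10, ..., 100}; whether an
  endorsed level could ever carry confidence 0 is left to the validator's
  documented rule rather than guessed.
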