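---
title: "Cognitive encoding models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive encoding models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogem)
```

## The model

A cognitive encoding model (CEM) predicts the activation of one cortical
region from an ontological annotation of the task being performed. Tasks
are described by a feature vector in $[0,1]^p$: mostly binary flags for the
presence of a psychological operation (e.g. visual word recognition, motor
planning), plus a few parametric features (e.g. the number of response
alternatives) recoded to $[0,1]$ by dense rank. For region $r$ with
activation $y_r$ (a z-scored condition-vs-rest contrast averaged over the
region's voxels), the model is linear,

$$ y_r = \mathbf{x}^\top \mathbf{w}_r + b_r + \varepsilon, $$

fit by ridge regression with an unpenalized intercept: feature columns and
responses are centered, the penalized normal equations solved (one
eigendecomposition of the centered Gram matrix serves every region and
every candidate penalty), and the intercept recovered from the means.
Features stay on their native $[0,1]$ scale — they are already commensurate
by construction, and standardizing binary indicators would reweight them by
task density.

Stacking all regions gives a whole-cortex predicted map for any feature
vector, including tasks never seen in training. That is the scientific
point: if the ontology captures what tasks share, a model fit on some tasks
should predict the activation pattern of new ones.

## Generalization testing

**Leave-two-out CV.** Every unordered pair of tasks is held out once
($\binom{n}{2}$ splits; 946 for a 44-task battery). All session rows of the
two held-out tasks are removed from training — inner folds also group whole
tasks, so the 2–4 session rows of one task never straddle train and
validation.

**Penalty selection.** Within each outer split, tasks are partitioned into
10 folds; for each penalty in the grid
$\{0.001, 0.01, 0.1, 1, 2, \dots, 10\}$ the model is fit on 9 folds and
every held-out row scored by the Pearson correlation between predicted and
observed region maps. The score is the mean over held-out rows (the
alternative — concatenating rows before correlating — is not what we use;
averaging weighs each task map equally). One penalty is chosen per outer
split, shared across regions, because the map-wise score already pools
regions. Ties go to the smallest penalty. With very small task sets the
fold count is clamped to the number of training tasks, so reduced-scale
runs remain well defined.

**Two-way classification.** Each held-out predicted map is independently
assigned to whichever of the two held-out tasks its session-averaged
correlation favors. A split is correct only if both maps go to their own
task. Because the two assignments are independent, a random classifier is
correct with probability $1/4$ — and a model whose predictions collapse
toward the training mean produces two near-identical maps that are forced
to the *same* task, which can never be correct. That mechanism pushes the
shuffled null (below) under chance rather than to it.

**Metrics.** Per held-out task: session-averaged Pearson $r$, and $R^2$
computed as the coefficient of determination about the observed map's mean
(it can be negative; we do not use squared correlation, which would hide
systematic offset — the choice matters for interpreting the null model's
small-but-positive $R^2$). Per subject these are averaged over the
$2\binom{n}{2}$ per-task values.

**Noise ceiling.** The explainable ceiling for a (subject, task) is
$\sqrt{r_{\text{between-session}}}$, the square root of the Pearson
reliability of the two session maps acquired at the same timepoint; tasks
observed at two timepoints average their two estimates. Non-positive
reliabilities leave the ceiling undefined; such estimates are excluded and
counted, not clipped to zero, because a clipped zero would masquerade as a
legitimate bound.

**Task-shuffled null.** Tasks are bijectively remapped so each task
inherits another task's feature vector; session blocks are preserved
(all 2–4 rows of a task receive the donor's vector), so column densities
are not. The full nested-CV pipeline is re-run per permutation, 20
iterations, and per-subject metrics averaged. The global identity
permutation is excluded; individual fixed points are allowed
(`forbid_fixed_points = TRUE` requests full derangements) — the choice is
logged with each iteration's permutation, reconstructible from
(seed, iteration).

## Downstream analyses

**Confusion structure.** Every predicted map's assignment increments a
task-by-task confusion matrix (row = true task). Rows are normalized to
probabilities before projecting into cognitive space by multiplication
with the feature matrix; normalization prevents tasks with more appearances
from dominating (raw-count projection is available via
`normalize = FALSE`). Features are then compared by a $1-r$
representational dissimilarity matrix and clustered with UPGMA
(average linkage on arithmetic means over member pairs), implemented
through `stats::hclust(method = "average")` with a Newick export; merge
ties follow hclust's deterministic internal order, and are measure-zero for
the continuous RDMs produced here.

**Between-subject transfer.** Each source subject's model is fit on all
tasks (penalty by the same inner 10-fold search) and evaluated by two-way
classification over every task pair on every target subject. The diagonal
(self-transfer) is computed identically to off-diagonal cells — it reuses
no cross-validated predictions, so it upper-bounds what transfer could
achieve.

**Network importances.** Coefficients are averaged across subjects first,
then across regions within each of the 7 resting-state networks — in that
order, since the network statistic is reported once rather than per
subject. Within- vs between-network similarity compares mean Pearson
correlations of region weight vectors over same- vs different-network
pairs, with a null from permuting region labels; the observed statistic is
included in the denominator, $p = (1 + \#\{d_{\pi} \ge d\})/(1 + B)$, so
$p$ is valid at small $B$ (default $B = 100$). Word-cloud tables keep only
positive-weight features and map magnitude linearly to relative size;
rendering is left to the user.

## The synthetic generator

Downstream stages are tested against data with known ground truth. The
generator emulates the structure of a dense-sampling multi-domain task
battery: 44 task conditions, 36 features (24 cognitive, 12
perceptual-motor; 3 parametric), 1000 cortical regions in 7 roughly
balanced resting-state networks, 23 subjects, and 14 tasks observed in four
sessions (two per timepoint) with the rest in two. Which tasks get four
sessions is a seeded random subset — the real battery's task-set overlap
identity is not reproduced, and the "14" is a free parameter since the
merged condition count makes the overlap ambiguous.

Generation: binary features are drawn at ~25% task density with constant
columns rejected (a constant column has unidentifiable weight); parametric
features draw raw magnitudes from a response-count-like pool and recode by
dense rank (tiny feature spaces, under 4 features, stay all-binary so
degenerate configurations fail loudly rather than by construction); task
rows are redrawn until pairwise distinct, with a bounded retry budget.
Ground-truth weights are unstructured Gaussians (SD 0.08) plus, per
network, 3–6 randomly chosen "signature" features mean-shifted by +0.4
across that network's regions. Subject weights perturb the group weights
(SD 0.04). A session map is
$\mathbf{x}^\top W_{\text{subj}} + c\,\mathbf{m} + \mathcal{N}(0,
\sigma^2)$ per region, where $\mathbf{m}$ is a task-general shared map
($c = 2$ by default) standing in for the common task-positive component of
real contrast maps, and $\sigma = 1.5$ z-units.

The default magnitudes were calibrated once so that, at the default scale,
single-subject two-way accuracy lands strictly between chance and 1
(≈ 0.68, with mean map $r$ ≈ 0.78 and mean noise ceiling ≈ 0.81) — the
regime in which the evaluation machinery is actually exercised. All
randomness flows through explicit integer seeds; the same seed reproduces
a study bit-for-bit.

What the generator does *not* emulate: hemodynamics and GLM estimation
(maps are drawn directly at the z-map level), spatial autocorrelation
between neighboring regions, heavy-tailed or subject-specific noise,
feature interactions, and annotation error. Passing tests therefore show
that the pipeline recovers what it assumes — a linear, additive,
spatially independent world — not that the assumptions hold in real data.

## Numerical choices and degenerate inputs

- Ridge solutions come from a symmetric eigendecomposition; penalties are
  strictly positive so the system is always well posed.
- Inner-CV scoring returns 0 (not NA) for a zero-variance prediction, so a
  degenerate constant fit scores poorly instead of crashing the search.
  User-facing metrics (`session_avg_corr`, `map_r2`) instead raise an
  explicit error on zero-variance maps.
- Classification ties break toward the first task and are flagged;
  they have probability zero for continuous data.
- Noiseless recovery (used in tests) additionally requires an identifiable
  design: the feature count must stay below the inner-loop training-task
  count, otherwise ridge predictions for held-out tasks are regularization-
  dependent. Test fixtures are chosen accordingly.
- Repeated-measures ANOVA is computed from the two-way decomposition
  (F = MS_set / MS_interaction with $(k-1, (k-1)(n-1))$ df), matching
  `aov(y ~ set + Error(subject/set))`.

## Problem sizes used by tests and scripts

The packaged test-suite and `scripts/acceptance.R` run the pipeline at
reduced scale, chosen as the smallest sizes at which each phenomenon is
stable: noiseless recovery at 8 tasks x 60 regions x 3 subjects; the
null-vs-model contrast at 8 tasks x 400 regions with a strong shared map
($c = 4$, $\sigma = 0.3$); monotonicity grids at 10 tasks x 60–300 regions;
the acceptance script's full pipeline at 24 tasks x 12 features x 1000
regions x 3 subjects (the region count is kept at full scale because
map-level discriminability grows with it). The analysis scripts under
`analysis/` use the same study configuration.

## Known limitations

Region-wise univariate models only; no feature interactions or nonlinear
mappings; no functional alignment across subjects; the dendrograms are
descriptive (no significance testing on tree structure); and the shipped
annotation loader expects the user's feature matrix — the package does not
bundle a curated ontology annotation.
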