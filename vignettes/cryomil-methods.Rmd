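---
title: "Methods: Transformer MIL for cryosection molecular diagnosis"
author: "cryomil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Transformer MIL for cryosection molecular diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Intraoperative diagnosis of diffuse midline glioma (DMG) relies on frozen
(cryo-) sections: a pathologist inspects each biopsy slide within minutes and
declares it *Pass* (adequate for diagnosis) or *No-Pass*, in which case the
surgeon may have to re-biopsy — a substantial risk for midline lesions.
Molecular markers that drive management (H3K27M, TP53, ATRX) are normally
only available days later from FFPE material. `cryomil` implements an
analysis pipeline in which a weakly supervised classifier predicts slide-level
molecular status directly from bags of cryosection patch features, explains
its predictions through attention, and quantifies — by replaying biopsy
sequences retrospectively — how many re-biopsies a correct early molecular
call would have avoided.

Real whole-slide cohorts are restricted-access; the package therefore ships a
synthetic cohort generator so that every stage, from tissue segmentation to
the re-checking simulation, runs and is tested end-to-end offline.

## The classifier

A slide is a bag $x \in \mathbb{R}^{N_x \times d}$ of $N_x$ patch feature
rows ($d = 768$ for the pathology foundation-model embeddings the pipeline is
designed around). One single-head self-attention Transformer block is
applied:

$$K = x W_K,\quad Q = x W_Q,\quad V = x W_V \qquad (d \to d_a)$$
$$A = \mathrm{softmax}\!\left(K Q^\top\right) \in \mathbb{R}^{N_x \times N_x}$$
$$y_{sa} = \mathrm{LN}\!\left(x + \mathrm{MLP}_{att}(A V)\right), \qquad
  y_{MLP} = \mathrm{LN}\!\left(y_{sa} + \mathrm{MLP}_{blk}(y_{sa})\right)$$

followed by mean pooling over the $N_x$ rows and a linear head with softmax
into (wild-type, mutant) probabilities. Design choices that the written
formulation leaves open, fixed here once and exposed in the hyperparameters:

* **Orientation and softmax axis.** Patches are rows; the score matrix is
  $(xW_K)(xW_Q)^\top$ and the softmax runs along the second (attended) index,
  so each row of $A$ is a probability distribution. `attention_forward()`
  asserts rows sum to 1.
* **No score scaling.** The scores are used unscaled; a conventional
  $1/\sqrt{d_a}$ factor is available behind `scale_scores = TRUE` but
  defaults off.
* **Dimensional repair.** $AV$ has width $d_a$ (64), so the post-attention
  MLP maps $d_a \to 1024 \to d$; otherwise the residual $x + \cdot$ would not
  conform. The block MLP maps $d \to 1024 \to d$. Both use ReLU between the
  two dense layers and no dropout.
* **Post-norm.** Layer normalisation is applied after each residual addition
  (`eps = 1e-5`).
* **No positional embedding.** The slide probability is therefore exactly
  invariant to patch order, which the tests quantify (max abs difference
  below 1e-6).

Training follows the reference configuration: 80 epochs of Adam at learning
rate 1e-4 with weight decay 5e-3 (classical L2 coupling into the gradient),
one bag per optimisation step, cross-entropy loss, and an
inverse-class-frequency weighted sampler drawing with replacement, epoch
length equal to the training-set size. Weights are initialised with uniform
fan-in scaling under the model seed; initialisation and the sampler stream
make training bit-deterministic given that seed. Forward and backward passes
are hand-written dense linear algebra; the gradients are validated against
central finite differences, and the whole forward pass against an
independent straight-line re-implementation, in the test suite.

## Attention explanation

Patch importance is the averaged logarithm of attention weights,
$W_i = \frac{1}{N_x}\sum_j \log A_{ij}$, clamped at $10^{-12}$ before the
logarithm because softmax can underflow. $A$ is not symmetric, so the
direction matters and the written sources for this statistic are ambiguous
between the two readings. `patch_importance()` exposes both:

* `"literal"` (default): the row average exactly as the formula is printed —
  the log-attention patch $i$ *pays out*; large when a patch spreads its
  attention narrowly.
* `"received"`: the column average — the log-attention patch $i$ *receives*
  from the rest of the bag, matching the "averaged logarithmic value for
  each column" description.

On trained synthetic cohorts, the received form is the one that tracks
informative patches: the enrichment check in the acceptance suite (fraction
of held-out mutant slides whose top-10 received-attention patches are
enriched for ground-truth signal patches) uses `convention = "received"`.
The literal row form measures attention concentration, which need not align
with signal; it remains the default because it is the printed formula.
Heatmaps (`attention_heatmap()`) are rendered at patch-grid resolution —
the statistic is per-patch — with missing cells flagged rather than filled.
Ranking by $W$ is invariant to the $1/N_x$ factor; ties in `top_patches()`
break to the lower index.

## Evaluation statistics

* **AUC** is computed by the rank (Mann–Whitney) formula with ties counted
  one half, and cross-checked against both an $O(n^2)$ pairwise oracle and
  pROC in the tests.
* **Operating thresholds.** "Balance between sensitivity and specificity" is
  operationalised as the maximum of Youden's $J = SEN + SPE - 1$ over
  midpoints of adjacent observed scores (ties take the lower threshold); a
  `min |SEN - SPE|` mode is selectable. F1 reporting uses a separate
  F1-maximising threshold search. Orientation is fixed: the score is the
  mutant-class probability, and a call is positive iff score ≥ threshold.
  In cross-validation, thresholds are estimated per fold on that fold's
  training predictions and the thresholded decisions are combined.
* **Confidence intervals.** For cross-validated results the interval is a
  t-interval over per-fold AUCs and the report tags it `fold-spread`; for
  one-time testing it is DeLong's structural-components interval (delegated
  to pROC, clipped to [0, 1]) tagged `DeLong`.
* **Significance.** One-sided permutation test with the add-one estimator
  $p = (1 + \#\{AUC_{perm} \ge AUC_{obs}\})/(n_{perm}+1)$, 1000 permutations
  by default, applied to the predictions pooled over folds for
  cross-validated results. Model-vs-model comparisons use a one-sided Welch
  t-test on per-fold AUCs. No multiple-testing adjustment is applied, and
  each report says which formula produced its interval.
* **Folds.** Cross-validation splits at the patient level (all slides of a
  patient share a fold — slide-level splitting would leak patients across
  folds), stratified by the patient-level task label so per-fold positive
  counts and fold sizes each differ by at most one; deterministic given the
  seed.

## The re-checking simulation

Each patient's slides are replayed strictly in arrival order. The *human*
count is the order of the first Pass slide (total count if none passed). The
*AI* count is the order of the first slide at which the model *accurately*
flags a mutant — by default under the strict reading: some gene must be both
truly mutant and predicted positive at its training-derived threshold (a
lenient any-positive mode is selectable). Patients with no mutant gene fall
back to the human count, and mutant patients the model never flags are
capped at the human count; the uncapped first-detection count is reported
alongside, since the convention for never-flagged patients is a declared
choice. Decision thresholds come from training folds (the mean of per-fold
balanced thresholds) and are never refit on the stream being scored. The
paired one-sided t-test (human > AI), Sankey transition counts
`Hn→Am`, and first/second-biopsy metrics (probabilities of the first two
samplings averaged per gene) complete the report. The whole analysis is
optimistic by construction — ground-truth mutation status is not available
intraoperatively — and every result object carries that caveat.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
histology. Per patient: independent per-gene mutant labels at configurable
prevalence (identical across the patient's slides), a pilocytic-astrocytoma
label, a centre, and a biopsy sequence in which biopsy $k$ is No-Pass with
probability `nopass_rate_by_order[k]`, continuing until a Pass or the
sequence cap (the vector length, default 6). Per slide: background patch
features are standard normal; each gene (and the PA label) owns a fixed unit
direction, orthogonalised across genes, and `round(fraction × N)` signal
patches (half-up; fractions 0.3 for Pass, 0.1 for No-Pass slides of mutant
patients) are shifted by `effect_size` along the mutant directions. No-Pass
mutant slides additionally shift a fraction (default 0.2) of background
patches by a weaker `peritumoural_effect` (default 0.5), emulating
peritumoural morphology cues; centres add a common offset
(`centre_offset_scale`, default 0.1) to all rows. All randomness derives
from one root seed through per-patient/slide child streams (stable string
hashing), so cohorts are reproducible independently of generation order.

Default rates were chosen once to match the published cohort shape — about
1.7 slides per patient with roughly 40% No-Pass slides in the primary
setting — via `nopass_rate_by_order = c(0.45, 0.35, 0.25, 0.15, 0.10, 0)`.
The Gaussian mean-shift emulation is a stand-in: real foundation-model
embeddings have unknown, certainly non-Gaussian structure, centre effects
are not purely additive, and signal patches are not i.i.d. draws. Passing
tests therefore demonstrate that the pipeline recovers structure it was
designed to recover, not clinical performance.

Synthetic slide images (white background, saturated elliptical tissue blobs,
optional marker strokes, blank holes, dust) exist purely to exercise the
preprocessing stage and return their own ground-truth tissue mask; marker
and hole pixels are excluded from the mask since they obscure or lack
tissue.

## Preprocessing

Segmentation runs a fixed pipeline: integer-factor area-average downscale
(factor 20 by default), RGB→HSV, threshold on saturation (default 8 on the
0–255 scale), median blur (kernel 7), morphological closing (disc, 4), then
removal of regions below `min_region_area` (default 100 downscaled pixels).
The defaults follow the biopsy-style preset of contour-based WSI pipelines;
the exact preset values are not published, so all are exposed. Median blur,
closing and connected components are delegated to EBImage. Patches
(224 px, stride = patch size) are kept iff their centre maps into a retained
region — the simplest deterministic inclusion rule — with 0-based, half-open,
top-left level-0 pixel coordinates (x = column, y = row), a convention that
heatmap back-mapping relies on. Quality filtering rejects a patch as
`blank` when mean RGB exceeds 230, or `contaminated` when more than 30% of
its pixels have all channels below 40.

## Problem sizes and numerical checks

Test and acceptance runs use desk-scale configurations chosen as the
package's own study conditions: cohorts of ~200 patients at feature
dimension 32 (attention dimension 16, MLP width 64, 20 epochs) for signal
recovery, five folds, and an effect size of 3 for the "strongly separable"
regime; statistical calibration uses 500 null replicates (permutation
type-I, 199 permutations each) and 5000 bi-normal replicates at n = 60 for
DeLong coverage, the larger count keeping the Monte-Carlo standard error of
the coverage estimate a few thousandths. Degenerate inputs are errors, not
silent defaults: empty bags, single-class label vectors, mismatched
dimensions and mask/image inconsistencies all raise typed messages, and
attention entries are floored at $10^{-12}$ before logarithms.

## Limitations

The pre-trained components that produce real patch features (the
cryosection-to-FFPE generative translator and the pathology foundation
model) are out of scope and represented only by a registry adapter that
validates shapes; bundled extractors (identity, seeded random projection)
are synthetic stand-ins. The generator does not model histology texture,
scanner optics, stain variation, or IHC readouts. The re-checking analysis
assumes ground-truth mutation status when scoring detections and is
explicitly optimistic; modelling pathologist–AI collaboration is out of
scope. BRAF and other lower-prevalence markers are not modelled.
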