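---
title: "Ordinal multi-instance learning with key-instance selection: models, design choices, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal multi-instance learning with key-instance selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oomil)
```

## The problem

Screening mammography distinguishes normal, benign, and cancerous
studies — three classes with a natural order (normal < benign < cancer).
Labels exist only at the image level: a radiologist grades the study,
not each region. `oomil` treats each image as a *bag* of patch
*instances* under the ordinal multi-instance assumptions:

* every instance has a (hidden) ordinal grade;
* no instance's grade exceeds its bag's label;
* the bag label equals the *strongest* instance grade present.

A normal bag therefore contains only normal tissue; a cancer bag
contains at least one cancerous region plus arbitrary lower-grade
content.

## The two-step model

Training alternates two operations per bag visit:

1. **Score and rank.** A small CNN maps every 224×224 patch to a scalar
   score \(s\). Each instance's loss against the *bag* label is computed
   under the current parameters, without gradients.
2. **Select and update.** The \(k\) minimum-loss instances (default
   \(k = 4\)) become the bag's *key instances*; they are assigned the
   bag label, their loss is recomputed with gradients, and one Adam step
   is taken on the mean. Selection is repeated at every visit, so the
   identity of the key instances is uncertain early and is refined as
   the score improves.

The intuition: the instances that already fit the bag label best are the
most plausible carriers of that label, so they — and only they — are
trained on it. `kid_stats()` summarizes how often the selected instances
are truly positive (the "S" diagnostic), and `render_selection()` draws
a bag with correct selections outlined in red and incorrect ones in
blue.

## The instance-scoring network

The reference stack, reproduced exactly at 224×224
(`network_spec()` defaults):

| layer | output | parameters |
|-------|--------|------------|
| Conv 5×5, 1→10 | 220×220×10 | 260 |
| ReLU, MaxPool 2×2/2 | 110×110×10 | 0 |
| Conv 3×3, 10→20 | 108×108×20 | 1,820 |
| ReLU, flatten | 233,280 | 0 |
| FC 500 (+ReLU) | 500 | 116,640,500 |
| FC head | 1 (or 3) | 501 |

`layer_output_side()` and `layer_param_count()` give these values in
closed form and the test-suite checks the built network against them.
The scalar head is the default; a 3-unit softmax head supports the
cross-entropy baseline. Convolutions are computed as im2col matrix
products with hand-written backward passes, so the package has no
deep-learning-framework dependency.

Two initialization modes exist. `paper_zero` sets every weight and bias
to zero — it reproduces a literal reading of the reference setup, but a
zero network has zero gradients through its ReLU stack and cannot
train; it is kept as a reproduction switch only. The default `standard`
mode uses fan-in-scaled He-normal hidden weights with zero biases, and
initializes the head as a *uniform positive, down-scaled* read-out of
the ReLU features. That head gives the initial score two properties
that matter for the selection dynamics (below): it responds
monotonically to patch intensity, and it starts below the first
cutpoint.

## The ordinal uncertainty loss

The loss used for ranking and training is the all-threshold
cumulative-logistic penalty on the scalar score with two trainable
cutpoints \(b_1 < b_2\):

\[
L(s, y) = \sum_{c \in \{0, 1\}} \mathrm{softplus}\!\big(z_c \,(s - b_{c+1})\big),
\qquad z_c = \begin{cases} +1 & y \le c \\ -1 & y > c \end{cases}
\]

Each term penalizes a violated ordering of the score against one class
boundary, so a confusion with an adjacent class never costs more than a
confusion with a distant one — the property that separates an ordinal
loss from plain cross-entropy. \(b_2\) is parameterized as
\(b_1 + \mathrm{softplus}(\delta)\), keeping the cutpoints strictly
ordered for any real \(\delta\); they initialize at 0.5 and 1.5, the
midpoints between consecutive class indices. Prediction thresholds the
score at the fitted cutpoints. Two alternatives sit behind the same
switch: a squared-error reading \((s - y)^2\) of the scalar head, and
the softmax cross-entropy used by the baseline comparison.

### Why thresholds get their own update rule

Three numerical findings shaped the trainer, all reproducible with the
package's own diagnostics:

* **Thresholds cannot share the network's Adam step.** Adam caps each
  parameter's movement near the learning rate, so two scalar cutpoints
  move by at most ~0.05 over hundreds of steps while the score
  distribution — moved by ~10⁵ cooperating weights — shifts an order of
  magnitude faster. Worse, Adam's per-parameter normalization turns the
  small cutpoint gradients into fixed-size steps whose direction is set
  by bag-label frequency alone (two of three labels push \(b_1\) down
  and \(b_2\) up), so the benign window simply expands. Cutpoints are
  therefore fitted by plain gradient steps at their own rate
  (`cutpoint_lr`, default 200× the weight rate) — the classical
  treatment of thresholds in cumulative-link ordinal regression.
* **Separable data makes the score scale diverge.** With cleanly
  separable synthetic classes the all-threshold loss has no finite
  minimizer — the ordinal analog of logistic regression under
  separation. The class clusters keep their relative geometry (the
  observed class-mean ratios stay near 1 : 1.6 : 2.5 for many epochs)
  while everything inflates multiplicatively. Threshold steps are
  therefore made *scale-equivariant*: they are multiplied by a running
  estimate of the mean selected |score|, so threshold fitting tracks
  the distribution at any scale.
* **Weight decay follows the named optimizer's convention.** The stated
  Adam weight decay (5e-4) is applied as L2 added to the gradient
  before the moment updates, which is what the referenced optimizer
  implementation does with its `weight_decay` argument; applied
  decoupled it would amount to 5e-8 per step and do nothing.

The remaining optimizer settings are used as stated: learning rate
1e-4, eps 1e-6, betas (0.9, 0.99), one bag per optimizer step, mean
over the \(k\) selected losses, selection redone under current
parameters at every visit, ties broken toward the lower instance index.

## The synthetic data generator

`synth_config()` emulates the statistical structure the method assumes,
not radiographic appearance. Images are tall grayscale fields
(448×224, so the 14×7 grid gives integer 32×32 cells) with Gaussian
background texture (mean 0.30, sd 0.03), a near-zero border band, and
0–3 lesion blobs: grade-1 lesions are smooth discs, grade-2 lesions add
a radial spicule perturbation — the benign-smooth versus
malignant-spiculated convention. Grades are ordered in appearance
(plateau intensities 0.55 and 0.85 against the 0.30 background), and
the generator guarantees the ordinal-MIL invariants: the maximum lesion
grade equals the bag label and no lesion exceeds it. A cell's hidden
instance label is the highest grade of any blob overlapping it by at
least one pixel.

Three generator choices came out of studying the training dynamics
rather than taste, and are worth recording:

* **Lesions occlude tissue** (composited with `max`, as a dense mass
  hides the parenchyma behind it) instead of adding to it. With
  additive bumps, a lesion patch is "tissue plus bump", and pushing
  lesion scores up drags the shared tissue features along — measured as
  the tissue score tracking the benign target for every loss choice.
* **Lesions cover at least as many grid cells as \(k\).** Training
  assigns the bag label to \(k = 4\) instances per visit; if a lesion
  occupies fewer than four cells, the selection is *forced* to include
  tissue instances, which are then trained with a positive label. The
  default radius (36 px against 32 px cells) makes the per-bag positive
  count consistent with \(k\).
* **The border fails the foreground filter outright.** Border cells
  that are 60% dark but pass the filter act as gradient sinks in
  normal bags: they are always the minimum-loss selection, their loss
  saturates near zero, and ordinary tissue never receives training
  signal. With the default 26 px border, all 38 border cells fall below
  the 0.25 foreground fraction, 60 tissue/lesion cells survive, and
  flip/rotate augmentation tops the bag up to 70.

The generator does **not** emulate pectoral muscle, compression
artifacts, vendor-specific intensity curves, DICOM metadata, or
physician-drawn region contours. Passing tests on this data show that
the selection-and-ordinal machinery works when per-patch evidence
exists and is brightness-monotone; they say nothing about performance
on real mammograms, where evidence is subtler and labels noisier.

## Problem sizes used by the test-suite

The architecture contracts are verified at the full 224×224 / 500-unit
scale. Training experiments run at a reduced scale chosen once: 32×32
instances (the native grid cells, so no upsampling is involved), a
64-unit FC1, 30 bags per class, \(k = 4\); 14 epochs for the
learning-accuracy checks across 3 seeds, 20 epochs for the
selection-precision trend at the high-contrast preset, 5 epochs for the
per-step selection-optimality audit. At these sizes the three
learning-sanity seeds reach instance-level test accuracies at or near
1.0 under the default initialization. The selection-precision trend run
uses `init_mode = "random_head"`: with the warm-start head, selection
picks the true lesions from the first epoch (precision ≈ 0.99
immediately), so there is nothing left to improve; with a randomly
oriented head the early selection is genuinely uncertain and precision
rises from roughly 0.73–0.78 in the first epoch to 0.96–1.00 in the
last — the behavior the E/K/S diagnostics are meant to display.

## Numerical details

* softplus is evaluated as `max(x, 0) + log1p(exp(-|x|))`; cross-entropy
  probabilities are floored at 1e-12.
* Bilinear resizing maps pixel centers, so a same-size resize is
  pixel-identical and constants stay constant; intensities clip to
  [0, 1].
* All randomness is derived from integer seeds through counter-based
  substreams (one per image, per epoch shuffle, per scorer), so
  datasets, selection histories, and loss traces are bit-reproducible;
  generation never perturbs the caller's RNG state.
* Selection ties break toward the lower instance index; trimming ties
  keep the earlier (row-major) patch.
* An image not divisible by the grid is center-cropped first; an
  all-background image errors out of `threshold_filter()` rather than
  producing an empty bag.

## Known limitations

* The loss realization is an interpretation: the published name
  ("minimum uncertainty ordinal loss") is not accompanied by a formula,
  and other readings (the squared-error variant is included) are
  possible.
* Min-loss selection trains each bag's best-fitting instances, so
  normal bags contribute little gradient once their selections
  saturate; the class-0 decision boundary is calibrated mostly by the
  threshold dynamics. On data without per-patch brightness monotonicity
  the warm-start orientation of the head would not help.
* The binary-decomposition baseline reuses this package's network and
  selection machinery, isolating the decomposition-versus-direct
  comparison rather than reproducing the historical baseline exactly.
* Training at the full 224-px scale (116.6M parameters) is supported
  but far too slow for routine use on a laptop CPU; the package is a
  study implementation, not a clinical tool.
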