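---
title: "Attention-weighted decision fusion for histopathology patches: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-weighted decision fusion for histopathology patches: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchfuse)
```

## The model

`patchfuse` implements a two-branch convolutional classifier for
hematoxylin-and-eosin (H&E) tissue patches with decision-level fusion.
Each branch is a no-top convolutional backbone producing a feature map
$A \in \mathbb{R}^{H \times W \times C}$. A $1{\times}1$ convolution with
sigmoid activation collapses the channels into a single spatial-attention
mask $M \in (0,1)^{H \times W \times 1}$, which is broadcast across channels
and multiplied element-wise into the map. The refined map is global-average
pooled to $g \in \mathbb{R}^{C}$, passed through a dense layer of width $h$
with ReLU, dropout, and a $c$-class softmax classifier giving the branch
prediction $p$.

The fusion stage concatenates $[p_a \,|\, p_b \,|\, g_a \,|\, g_b]$ and maps
it through a dense layer with softmax to two instance-specific weights
$w = (w_1, w_2)$ on the simplex. The fused prediction is

$$\hat{y} = w_1\, p_a + w_2\, p_b,$$

which stays on the $c$-simplex by construction. Unlike soft voting or
stacking with fixed coefficients, $w$ is recomputed per instance, so the
network can lean on whichever branch is more reliable for a given patch.
Training attaches a single categorical cross-entropy loss to the fused
output; the branch classifiers receive gradient only through the fusion
path. This is the minimal reading of the architecture — no auxiliary
per-branch losses — and it keeps the loss surface consistent with what the
fused prediction optimizes. The fusion input uses the GAP-pooled
attention-weighted vectors (lengths $d_a + d_b$), not flattened maps or the
dense-layer activations: that choice is the only one under which the
layer-by-layer parameter accounting reconciles with the published totals
for all three backbone pairings (see below).

## Parameter accounting

For branch feature widths $d_a, d_b$, class count $c$ and head width $h$,
the custom head contributes

$$(d_a{+}1) + (d_b{+}1) + h(d_a{+}1) + h(d_b{+}1) + 2c(h{+}1)
  + 2(2c + d_a + d_b + 1)$$

parameters (two attention convolutions, two branch dense layers, two branch
classifiers, the fusion layer). Adding the canonical no-top counts of the
ImageNet backbones reproduces the published totals exactly:

```{r}
total_parameter_count(fusion_config("inceptionv3", "xception", 3))
total_parameter_count(fusion_config("xception", "mobilenet", 3))
total_parameter_count(fusion_config("inceptionv3", "mobilenet", 3))
```

The three backbone no-top counts (InceptionV3 21,802,784; Xception
20,861,480; MobileNet 3,228,864) are the unique solution of the linear
system formed by these three totals and the head formula, and equal the
no-top counts of the canonical reference implementations. The registry
stores the large backbones as opaque specifications — feature shape, input
shape and parameter count — because reconstructing their hundreds of
pretrained layers is neither possible offline nor needed for any analysis
in this package: assembled models instantiate the head weights concretely
and are counted by enumeration, and the test suite verifies that the
enumerated and analytic counts agree. Forward passes and training run on
the registered `tiny` backbone, a real two-layer convolutional stack
(32×32×3 input, 7×7×16 features, 1,392 parameters) built for desk-scale
experiments. The whole differentiable stack — convolutions via im2col,
attention, pooling, dense heads, softmax fusion, Adam — is implemented in
base R matrix algebra and validated against central-difference numerical
gradients.

## Training protocol

Defaults in `training_config()`:

| parameter | default | role |
|---|---|---|
| learning rate | 1e-4 | Adam initial step size |
| schedule | ÷10 every 10 epochs from epoch 10, floor 1e-6 | step decay |
| epochs | 50 max | upper bound; early stopping usually fires first |
| batch size | 32 | minibatch SGD granularity |
| dropout | 0.5 | head regularization, inactive at inference |
| patience | 10 | epochs of non-improving validation loss tolerated |
| restore best | yes | final weights are the best-validation-loss weights |
| unfrozen top layers | 20 | per-backbone fine-tuning depth |

Improvement means a strict decrease of validation loss (no minimum delta).
The validation split carved from the training partition is 15% by default,
seeded. The freezing policy is applied per backbone — each branch unfreezes
its own top layers — because counting over the combined layer list would
fine-tune only one branch, contradicting the symmetric design; the
combined-counting mode remains available via `freeze_mode = "combined"`.
Desk-scale runs in the tests use a larger base rate (3e-3 to 1e-2) because
the tiny backbone trains from random initialization rather than from
pretrained weights; the schedule, stopping and restoration logic are
identical at every scale.

Baseline single-backbone classifiers (backbone → GAP → dense → dropout →
softmax) train under the same protocol. The harness fine-tunes baselines by
default and offers a frozen-backbone mode (`frozen_baseline = TRUE`),
since both evaluation conventions appear in practice.

## Evaluation metrics

Confusion matrices are rows = actual, columns = predicted, with real-valued
entries so fold-averaged matrices reuse the same machinery. Per-class rates
are one-vs-rest: sensitivity $TP/(TP{+}FN)$, specificity $TN/(TN{+}FP)$,
precision $TP/(TP{+}FP)$, F1 the harmonic mean. Matthews correlation uses
the standard binary denominator
$\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}$ and, for $k > 2$, the
standard multi-category matrix form — one coefficient per matrix, which is
the convention used for dataset-level reporting. Cohen's kappa is
$(P_o - P_e)/(1 - P_e)$; a `strict_printed` flag reproduces the
non-standard variant that divides by $(1 - P_o)$, kept only for comparison
with reports that use it. Zero denominators yield 0 with a logged warning —
this arises only in degenerate desk-scale runs where a class is never
predicted. A single-cell matrix makes kappa undefined ($P_e = 1$) and is an
error. Accuracy and misclassification rate are complementary percentages by
construction.

Split sizes use ceiling rounding ($|test| = \lceil 0.15\,n \rceil$), the
unique convention reproducing all six published test-set sizes (545, 506,
270, 385, 408, 518) from the dataset totals. The default split is uniform
(non-stratified); small synthetic sets can request stratification. K-fold
plans are seeded shuffled partitions with fold sizes differing by at most
one; the mean fold matrix therefore sums to $n/k$ exactly.

## Grad-CAM

Channel weights are spatial means of the gradient of a class score with
respect to a convolutional activation; the heatmap is the ReLU of the
weighted channel sum, normalized to max 1 (an all-zero map stays all-zero
rather than dividing by zero), and bilinear-upsampled to input resolution.
The class score is the pre-softmax logit — standard practice, and it makes
heatmaps invariant to shifting all logits by a constant. For the fusion
model the default target is each branch's attention-multiplied feature map;
the two upsampled branch maps are combined with the instance's fusion
weights into a single display map. This combination rule is this package's
convention (recorded in the result's `target_layer` metadata); single-branch
maps are available via the `target` argument. Overlays use a fixed,
closed-form jet-style colormap so exports are bit-reproducible.
`localization_score()` binarizes a heatmap at an upper quantile and reports
intersection-over-union against a ground-truth mask — a quantitative
stand-in for expert review of highlighted regions.

## Synthetic data

The generator produces H&E-palette texture patches for six motif kinds —
glandular rings (mucosa), oriented fibers (stroma), binarized speckle
(debris), bright vacuoles (adipose), wavy bands (muscle), dense dark
nuclei (lymphoid) — each a deterministic grayscale field mapped through a
two-anchor purple/pink palette plus Gaussian pixel noise (sd 0.03). The
class palettes and motif spectra differ enough that a small classifier
separates them reliably, which is the point: the fixture is informative,
not noise. Randomness is counter-based — each patch's RNG stream is derived
from (global seed, class, item index) — so any item is bit-reproducible
independent of generation order. Patch counts can mirror the published
per-class profiles (`crc_dataset_profiles()`; eighteen counts totalling
17,531).

What the generator does *not* emulate: stain variability and scanner
response, intra-class morphological heterogeneity, spatial correlations
across neighbouring patches, label noise. Passing tests on synthetic data
therefore demonstrate that the architecture, training loop, bookkeeping and
interpretability machinery behave as specified — not that the tiny models
would transfer to real slides. Planted-signal fixtures add a contrasting
dark-nuclei disc (default 10% of the image area, amplitude 0.9) with its
mask, giving Grad-CAM localization a ground truth; trained desk-scale
models localize the disc far above the Monte-Carlo chance level
(IoU ≈ 0.05 for random maps at the top-decile threshold).

## Numerical choices

- Weight init: Glorot-uniform, zero biases, seeded per model; attention and
  fusion layers included.
- Cross-entropy clips probabilities at 1e-12 before the log.
- Dropout is inverted (activations scaled by 1/keep at train time), so
  inference needs no rescaling.
- Adam uses the customary (0.9, 0.999, 1e-8) moments with bias correction.
- Argmax ties resolve to the lowest class index (`which.max`/`max.col`
  with deterministic tie-breaking in prediction paths).
- All experiment-level randomness (splits, folds, shuffling, dropout,
  synthetic patches) flows through explicit seeds; reruns reproduce every
  split index and confusion-matrix entry bit-for-bit.

## Problem sizes used by the test suite

Desk-scale conditions keep the full pipeline exercised end to end: the
tiny backbone at 32×32 input; a 300-image three-class set (100 per class)
for the fusion-vs-baseline comparison, trained 20 epochs at base rate
3e-3; a 60-image planted-signal fixture trained 30 epochs at 1e-2 for
localization; 150 Adam passes for the fusion-gate recovery scenario; and
1,000 random 2×2 matrices for metric-oracle agreement. These sizes were
chosen as the smallest at which the qualitative claims are stable across
seeds.

## Known limitations

- The ImageNet backbones are parameter-accounting specifications; forward
  passes require a backbone with instantiated weights (the `tiny` registry
  entry, or any backbone registered with a builder).
- Training is single-threaded base R and intended for desk-scale
  verification, not production fitting of 46M-parameter models.
- No stain normalization, augmentation, or whole-slide tiling: patches are
  assumed pre-extracted, as in the class-per-subdirectory layout.
- The fusion architecture supports exactly two branches.
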