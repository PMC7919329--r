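---
title: "Segmenting liver and tumor in CT slices with a reduced-filter U-Net"
author: "livseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting liver and tumor in CT slices with a reduced-filter U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livseg)
```

## The problem

Liver cancer is usually assessed on contrast-enhanced abdominal CT. On an
axial slice, the liver is a large, fairly homogeneous region brighter than
most of its surroundings, and lesions appear as focal areas that are
darker (hypodense) or brighter (hyperdense) than healthy liver
parenchyma. Delineating liver and lesions by hand across the ~150 slices
a liver typically spans is slow, so automatic semantic segmentation is
the standard approach.

Two properties of this data dominate the design of any segmentation
model. First, extreme *class imbalance*: pooled over slices, liver
foreground is roughly one pixel in ten and tumor foreground roughly one
in 86, so a per-pixel loss is swamped by background. Second, scarce
annotated data, which makes aggressive augmentation and small models
attractive.

`livseg` implements a three-model pipeline around a *reduced-filter
U-Net*: one model segments the liver from the abdominal slice, one
segments tumor from the liver-masked slice, and one segments tumor
directly from the abdominal slice. Class imbalance is attacked twice:
with a weight factor in the dice loss, and — the pipeline's
distinguishing step — by *removing slices without target foreground*
from the training pool before training.

## The network

The architecture is an encoder–decoder with skip connections:

* **Contracting path** — 4 blocks, each two units of (3×3 convolution,
  same padding → ReLU → batch normalization), then 2×2 max pooling and
  dropout (rate 0.5). Filters start at 16 and double per block: 16, 32,
  64, 128.
* **Bottleneck** — two convolution units of the same form.
* **Expanding path** — 4 blocks, each a 2×2 stride-2 transposed
  convolution (halving channels, doubling resolution), concatenation
  with the matching contracting-path feature map, then two convolution
  units.
* **Head** — a 1×1 convolution to one channel with a sigmoid; masks are
  produced by thresholding at 0.5.

For a 128×128 input the encoder resolutions are 128 → 64 → 32 → 16 → 8.
The reduced width matters: the base-16 model has about 1/18 of the
parameters of the equivalent base-64 network (`countParameters()`
verifies the exact census), trains proportionally faster, and loses
nothing on these tasks.

Two architectural points were genuinely open and are settable in
`architectureConfig()`:

* **Bottleneck width.** The description of the contracting path ends at
  128 filters without fixing the bottleneck. The default follows the
  standard U-Net doubling (256); `bottleneck = "same"` keeps 128.
* **Normalization order.** The blocks are described as convolution with
  ReLU activation *and then* batch normalization; the default implements
  that literally (`conv-relu-bn`), with the more common `conv-bn-relu`
  available. Dropout is applied only in the contracting path, after
  pooling, as described.

Because all convolutions use same padding, encoder and decoder feature
maps align exactly and no cropping is needed before concatenation.

The forward and backward passes are implemented natively (im2col +
single-precision BLAS GEMM in C++, with analytic gradients for every
layer), so the package has no deep-learning framework dependency. The
backward pass is verified in the test suite against directional finite
differences through the whole network.

## Losses and class weighting

Training uses one of two losses on the sigmoid output $p_i \in (0,1)$
against the binary target $y_i$:

* **Weighted dice loss**
  $\mathcal{L} = -W\,\frac{2\,TP + \varepsilon}{2\,TP + FP + FN + \varepsilon}$,
  with soft counts $TP = \sum_i p_i y_i$, $FP = \sum_i p_i (1-y_i)$,
  $FN = \sum_i (1-p_i) y_i$ so the loss is differentiable (with soft
  counts the denominator reduces to $\sum_i p_i + \sum_i y_i$). $W > 0$
  rescales the loss against class imbalance; the loss is exactly linear
  in $W$ and reaches $-W$ at a perfect prediction. The smoothing
  constant $\varepsilon = 1$ defines the empty-prediction/empty-target
  case as perfect ($-W$). `estimateWeight()` offers a fixed $W$
  (default 1) or the pooled background:foreground ratio
  (`inverse-ratio`); with the Adam optimizer a constant $W$ mostly
  rescales the gradient, so the default is the neutral 1.
* **Binary cross-entropy**
  $\mathrm{BCE} = -\tfrac1N \sum_i y_i \log p_i + (1-y_i)\log(1-p_i)$,
  with each log argument clipped below at $10^{-7}$ so confident
  mistakes stay finite while perfect predictions score exactly 0.

By convention of the three-experiment design, the liver and
tumor-from-liver models default to the weighted dice loss and the
tumor-from-abdomen model to BCE; `trainConfig()` can override either.

## Class balancing by slice filtering

`filterSlices()` keeps exactly the slices whose target mask contains at
least one foreground pixel ("no information" means zero foreground — no
minimum-area cutoff). The imbalance statistic is the white:black pixel
ratio $\mathrm{Ratio} = N_\mathrm{white}/N_\mathrm{black}$, pooled over
slices; the returned `ClassBalanceReport` carries it before and after
filtering. Removing empty slices can only raise the pooled ratio, and
the acceptance suite shows the behavioral consequence on phantoms:
tumor models trained on filtered data beat unfiltered training on
held-out tumor DSC in every repetition tried.

## The phantom generator

Real liver-CT training corpora cannot ship with a package, so
`phantomConfig()`/`generateSlice()`/`generateVolume()` synthesize
axial-slice look-alikes with exact ground truth:

* the liver is a randomly placed, rotated ellipse (semi-axes drawn from
  14–21.5% of the image side) with a low-frequency boundary
  perturbation (two harmonics, amplitude up to 5%) so it is not a
  perfect conic;
* lesions are 1–2 disks per lesion-carrying slice (60% of slices),
  radii 3–6.8% of the side, placed by rejection sampling entirely
  inside the liver, hypodense by default (contrast −0.3 on liver
  intensity 0.6 over background 0.2);
* Gaussian noise (sd 0.05) is added and intensities clamped to [0, 1] —
  phantoms are generated directly on the normalized scale, with no
  Hounsfield-unit simulation;
* `generateVolume()` prepends and appends empty (liver-free) slices,
  emulating the start and end of an abdominal scan, which is exactly
  what the slice filter is meant to discard.

The geometric defaults were calibrated once, by Monte Carlo over 1000
slices, to the class-imbalance regime of real liver/tumor masks: pooled
liver ratio ≈ 1:9.2 and pooled tumor ratio (over lesion-carrying
slices) ≈ 1:87. The pooled interpretation was chosen because the
imbalance statistic is a dataset-level property; per-slice ratios vary
widely by construction.

What the phantoms do *not* emulate: organ texture, neighboring organs
of similar intensity, partial-volume effects, irregular lesion shapes,
3D lesion continuity, or scanner physics. Passing the phantom
experiments therefore demonstrates that the implementation learns and
segments under the intended geometry and imbalance — not that it
reaches any particular accuracy on clinical CT.

## Augmentation

Training uses on-the-fly affine augmentation: each epoch draws a fresh
transform per slice (`sampleTransform()`), applied identically to image
and mask (`applyTransform()`), bilinear for the image and
nearest-neighbor for the mask so it stays strictly binary. Ranges are
deliberately conservative, since axial anatomy keeps its orientation:
rotation ±10°, shift ±5% of the side, zoom 0.9–1.1, shear ±5°,
horizontal flip. These ranges are an explicit package choice — the
method prescribes affine deformation but no magnitudes. Elastic
deformation is excluded on purpose: the deformation family here is
affine only. A degenerate configuration (all ranges zero, flip off) is
detected and bypassed, so it reproduces the unaugmented pipeline
bit for bit.

Geometric fine print: the warping backend addresses pixel *i* at
coordinate *i* − ½, so rotations are taken about the true image center;
identity parameters return the input unchanged; `fillMode` chooses
between zero padding and edge replication for exposed regions.

## Training protocol

`trainConfig()` defaults encode the reference protocol: batch size 8,
250 epochs, validation split 0.30, Adam with learning rate 0.0001,
dropout 0.5. Per epoch the history records the optimized batch loss and
batch DSC (dropout active), plus validation loss and DSC in inference
mode (running batch-norm statistics, thresholded predictions). The
best-validation-DSC parameter snapshot is retained alongside the
final-epoch weights. The validation split is random per slice;
per-patient grouping is a realism refinement the phantom data cannot
express.

The test and acceptance runs use scaled-down problem sizes chosen as
this package's own desk-scale study conditions: 64×64 phantoms, 200
slices, 30 epochs for the two experiments, an 8-slice/50-epoch
memorization probe, and five repetitions of the filtered-vs-unfiltered
comparison at 60 slices/8 epochs. With schedules compressed roughly
8-fold relative to the 250-epoch reference protocol, the experiments
use Adam's conventional 1e-3 (and the memorization probe 5e-3, where
rapid overfitting is the point); the 1e-4 reference rate is tuned to
the long schedule and is retained as the package default.

## Numerical choices

* Convolution arithmetic runs in single precision (the standard CNN
  precision); everything crossing the R boundary is double. Batch-norm
  statistics and reductions are computed in double.
* Batch-norm $\varepsilon = 10^{-5}$, running-stat momentum 0.9.
* He initialization for convolution weights; BN scale 1, shift 0.
* Dice smoothing $\varepsilon = 1$; BCE clip $10^{-7}$; prediction
  threshold 0.5 (`predictMask(..., threshold = )` to change).
* Min–max normalization is per slice (slices are the training unit);
  a constant slice normalizes to zeros with a warning.
* Masks are resized/warped with nearest-neighbor; any interpolated mask
  is re-thresholded at 0.5.
* Empty-empty mask pairs score DSC = JSC = 1, so lesion-free slices
  count as perfect when correctly left empty; `evaluateMasks()` reports
  both the per-slice mean (headline) and pooled-count aggregation, and
  both the sd and the se of the per-slice DSC.

## Limitations

* Phantom geometry is far simpler than clinical CT; results here bound
  implementation correctness, not clinical accuracy.
* The engine is CPU-bound and 2D; it is sized for small studies, not
  for training on full public CT corpora.
* Only affine augmentation and binary (single-foreground) targets are
  supported; multi-class segmentation would need a softmax head.
* NIfTI support covers the plain 3D volume + combined {0,1,2} label
  convention; DICOM series are out of scope.
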