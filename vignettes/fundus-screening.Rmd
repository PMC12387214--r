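---
title: "Lightweight attention-augmented CNN screening for retinal fundus images"
author: "fundusnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight attention-augmented CNN screening for retinal fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusnet)
```

## The problem

Automated screening of color fundus photographs must cope with three
obstacles at once: severe class imbalance (rare but critical diseases),
limited compute at the point of care, and the need for visual evidence a
clinician can check. `fundusnet` implements a complete pipeline built around
a compact attention-augmented convolutional network for ten-class retinal
disease classification, with feature-space SMOTE class balancing, stratified
splitting, on-the-fly augmentation, per-class evaluation and integrated
Grad-CAM / Grad-CAM++ saliency. A procedural synthetic-fundus generator
makes every stage testable without any external image download.

## The model

Let $X \in \mathbb{R}^{H \times W \times C}$ be a feature map,
$\phi(\cdot) = \max(0, \cdot)$ the ReLU, $\sigma$ the logistic sigmoid,
$\mathrm{BN}$ batch normalization and
$\mathrm{GAP}(X) = \tfrac{1}{HW}\sum_{ij} X_{ij\cdot} \in \mathbb{R}^C$
global average pooling. The trunk composes four ingredients:

* **Depthwise separable convolution**: a per-channel $3\times3$ spatial
  convolution followed by a $1\times1$ cross-channel projection to $F$
  channels,
  $\mathrm{DSConv}_{C\to F}(X) =
   \phi(\mathrm{BN}(\mathrm{Conv}_{1\times1}(\phi(\mathrm{BN}(Y^{dw})))))$.
* **Squeeze-and-excitation (SE)**: channel gates
  $\mathrm{SE}(X) = \sigma(W_2\,\phi(W_1\,\mathrm{GAP}(X))) \odot X$ with a
  bottleneck of reduction ratio $r = 16$ (gates strictly in $(0,1)$).
* **Global-context (GC) attention**:
  $\mathrm{GC}(X) = (1 + \sigma(W_g\,\mathrm{GAP}(X))) \odot X$ (channel
  scales strictly in $(1,2)$).
* **Residual block**: two $3\times3$ convolutions (BN after each, ReLU after
  the first) plus a $1\times1$-projected skip, summed with *no* trailing
  activation.

The full network is: a $3\times3$, 64-filter stem (BN, ReLU, $2\times2$
max-pool), then four blocks widening $64 \to 128 \to 256 \to 512 \to 1024$
channels — DSConv+SE, DSConv+GC, DSConv+SE, residual — each followed by a
$2\times2$ max-pool with floor semantics, then GAP and a dense head
$1024 \to 512$ units (ReLU, dropout $0.5$ after each) with a softmax output
over $N = 10$ classes. For $150\times150\times3$ inputs the spatial trace is
$150 \to 75 \to 37 \to 18 \to 9 \to 4$.

```{r}
spec <- defaultArchitecture()
spatialTrace(spec)
countParameters(buildModel(spec, seed = 1))
```

Training minimizes the batch cross-entropy plus an $\ell_2$ penalty
$\lambda\lVert\theta\rVert_2^2$ with $\lambda = 0.01$, using Adam
($\eta = 10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$, batch 32, up to 50
epochs) with reduce-on-plateau (factor 0.5, patience 5, floor $10^{-6}$) and
early stopping (patience 15, best weights restored).

### Design choices where the design was open

* **Head widths.** Two readings of the classification head are possible: a
  $1024 \to 512$-unit head, or a $512 \to 512$ one. Only the former
  reproduces the published parameter budget of 16,552,114 trainable
  parameters — verified here by exact closed-form accounting — so it is the
  one implemented.
* **Bias and BN placement.** Every convolution (including depthwise) and
  every dense layer carries a bias; BN sits after the stem convolution,
  after both halves of each depthwise separable convolution and after all
  three residual-block convolutions. This is the unique convention that
  reproduces both the trainable count and the 8,960 non-trainable
  moving-statistics count ($2$ per BN channel over $4{,}480$ channels).
* **SE bottleneck width** is $\lfloor C/r \rfloor$; a configuration whose
  reduced width would be zero is rejected.
* **$\ell_2$ scope.** The penalty is applied to the hidden dense-layer
  kernels of the head (where the regularization is specified); a config
  switch (`l2Scope = "all"`) enables global decay instead.
* **Callback monitors.** Plateau reduction and early stopping monitor
  validation loss; the checkpoint keeps the weights with the best validation
  accuracy. Improvement thresholds are zero, the last partial batch is kept,
  and training indices are reshuffled each epoch from the run seed.
* **Numerics.** Softmax subtracts the row maximum (value-preserving);
  BN uses $\varepsilon = 10^{-3}$ and moving-statistic momentum $0.9$ — a
  deliberate package default so that short desk-scale schedules still leave
  the inference statistics close to the data; true-class probabilities are
  clamped at $10^{-12}$ in the loss (with a warning); weights use He fan-in
  initialization from a caller-supplied seed, biases start at zero.

## Data pipeline

`loadDataset()` reads a one-subdirectory-per-class image tree, resizes
bilinearly to $150\times150$, converts to RGB and maps 8-bit intensities to
$[0,1]$; class indices are 0-based positions in the sorted directory list,
recorded in a manifest.

**SMOTE.** Balancing happens in feature space on flattened pixels: every
class is raised to the majority count by synthesizing
$s = x + u\,(x' - x)$, $u \sim U(0,1)$ (one draw per sample), with $x'$ one
of the $k = 5$ nearest same-class neighbors under the Euclidean metric.
Originals are preserved unchanged. Because full-resolution neighbor search
is memory-heavy, `smoteBalanceImages()` can run the *search* on bilinearly
downscaled copies while interpolating full-resolution pixels; the planned
(seed, neighbor, $u$) triples are identical in either case. Balancing
precedes the split by default — the published order, which the test supports
(226/227 per class) confirm — although it leaks interpolated information
across folds; `split_first` reverses the order and then balances only the
training fold.

**Stratified split.** 70/15/15 by largest-remainder rounding: global split
totals are fixed first (ties toward the later split), then per-class cells
are filled greedily by fractional remainder under those totals with seeded
tie-breaking, so every class lands within one sample of its exact quota. On
the balanced $10 \times 1509$ set this yields test supports of 226 or 227
per class, 2,264 in total.

**Augmentation** draws, per training image and epoch: rotation within
$\pm20^\circ$, width/height shifts within $\pm10\%$, shear and zoom within
$\pm10\%$, and a horizontal flip with probability 0.5 — composed into one
inverse-mapped affine warp with bilinear sampling and clamp-to-edge fill,
then clipped to $[0,1]$. Augmentation is on-the-fly (the dataset is never
inflated) and applies only to the training stream.

## Evaluation

`confusionMatrix()` tallies true (rows) against predicted (columns) classes;
`classificationMetrics()` derives one-vs-rest TP/FP/FN per class, precision
$TP/(TP+FP)$, recall $TP/(TP+FN)$, their harmonic-mean F1, unweighted macro
averages and overall accuracy (trace over total). Zero-denominator metrics
are reported as 0 with a warning, matching how degenerate classifiers are
conventionally tabulated. Reports round to 3 decimals in their printed form.

## Explainability

`gradCAM()` taps a spatial layer (default: the residual-block output before
the final pool, the highest-resolution deep feature map), computes the
gradient of the *pre-softmax* class score with respect to the tapped
activations by exact backpropagation, averages it over space into channel
weights, and rectifies, bilinearly upsamples and min-max normalizes the
weighted channel sum. `gradCAMpp()` forms position-wise weights
$\alpha = g^2 / (2g^2 + \sum_{ab}A_{ab}\,g^3 + \varepsilon)$ from
derivatives of $\exp(y^c)$ (which reduce to $e^y g^k$ for a logit target)
and channel weights $\sum_{ij} \alpha_{ij}\,\phi(g_{ij})$. Guards: an
all-zero rectified map is returned as zeros (no division when max = min) and
$\alpha$ denominators carry $\varepsilon = 10^{-8}$. `overlayHeatmap()`
blends $(1-\alpha)\,\mathrm{image} + \alpha\,\mathrm{colormap(map)}$.

## The synthetic-fundus generator

The generator renders a circular retinal field (radial falloff, warm
coloration, smooth low-frequency texture, a small temporal optic disc) and
plants one caricatured, class-specific lesion program per class — scattered
dark microlesions (diabetic retinopathy), a bright neuroretinal ring with a
dark cup (glaucoma), a swollen bright disc (disc edema), a bluish central
blister (central serous chorioretinopathy), a pale inferior macular patch
(macular scar), a nasal wedge (pterygium), a pale peripheral fold (retinal
detachment), peripheral pigment speckle (retinitis pigmentosa), tessellated
texture (myopia), and a clean field (healthy). Default per-class counts
follow the printed study distribution (1509, 1349, 101 and 17 for the four
published classes; the remaining six are approximations chosen to total
5,335).

Each image records a lesion *bounding region* (0-based, half-open pixel
intervals). The region includes a margin of $0.12\,S$ — about half a
block-4 tap cell, since the network pools by $16\times$ overall and CAM
peaks are therefore quantized to that grid; localization claims cannot be
sharper than the tap resolution. Classes whose signature is global
(diabetic retinopathy, retinitis pigmentosa, myopia, healthy) are flagged
non-localized and excluded from containment statistics.

What the generator does *not* emulate: vasculature, camera vignetting and
specular artifacts, intra-class disease grading, inter-camera color shifts,
or any clinically realistic lesion morphology. Passing tests on this fixture
demonstrate that the pipeline's machinery — balancing, training, metrics,
saliency — functions and that the network can learn separable image classes;
they say nothing about clinical performance on real fundus photographs,
which requires GPU-scale training on the external dataset.

## Desk-scale benchmark

The test suite trains a reduced-width twin of the architecture (stem 8,
blocks 16/32/64/128, head 128/64 — identical topology and attention plan) on
64-pixel synthetic images, 40 per class, with the standard augmentation
ranges, Adam at $2\times10^{-3}$ (a faster schedule suited to the small
model; the $10^{-4}$ default belongs to the full-scale network) and 30
epochs, repeated over three seeds. Under these conditions the held-out
macro-F1 is expected $\geq 0.6$ seed-averaged (in practice it approaches
1.0) and Grad-CAM peaks fall inside the planted lesion regions in $\geq 70\%$
of held-out localized-lesion cases. These problem sizes keep the whole suite
a matter of minutes on a single CPU.

## Known limitations

* The engine is a faithful but compact reimplementation: single-threaded
  CPU numerics (R + C++ kernels), suitable for the desk-scale benchmark and
  for building the full model; training the full-scale network on a real
  5,335-image dataset is a GPU-class workload out of scope here.
* SMOTE on raw pixels inherits the published design's leakage when balancing
  precedes splitting; use `split_first` when that matters.
* Checkpoints use R serialization (plus a JSON architecture sidecar); they
  are not interchangeable with other frameworks' weight formats.
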