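---
title: "Methods: bone-age assessment with ambiguous label distributions"
author: "BoneAgeDL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bone-age assessment with ambiguous label distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoneAgeDL)
```

## Problem and model

Bone-age assessment estimates skeletal maturity from a hand radiograph.
Routine clinical reports state the age ambiguously — *"approximately 9
years old"* (a point statement) or *"12–13 years old"* (an interval). This
package models such labels as **distributions** over `r boneAgeBins()`
monthly bins $l_i = i$, $i = 1, \dots, 240$ (month 0 is excluded: reports
never assert a bone age of zero), and trains a multi-branch pipeline whose
every branch predicts a distribution over the same bins.

### Label codec

A report string is parsed into a point or interval label; the centre $\mu$
is the stated value (converted to months) for points and the interval
midpoint for intervals. The label distribution is the renormalized Gaussian

$$y_i = \frac{\varphi\!\left((l_i - \mu)/\sigma\right)}
             {\sum_j \varphi\!\left((l_j - \mu)/\sigma\right)},$$

with $\sigma = 3$ months by default — wide enough to spread mass over a
clinically meaningful neighbourhood, narrow enough that the mode stays at
$\mu$ for all in-range $\mu$. Decoding is the expectation
$\hat a = \sum_i l_i \, p_i$ (an argmax readout is also provided).

**Numerical note (truncation bias).** Renormalization over a finite bin
range biases the expectation readout toward the range centre. The bias at
$3\sigma$ from the edge is about $0.012$ months for $\sigma = 4$ and falls
below $10^{-3}$ months beyond $5\sigma$; the unit tests assert exactly
these bounds rather than a spuriously tight one.

### Hand localization (HOLM)

Backbone features $F \in \mathbb{R}^{H\times W\times K}$ are projected by
the trainable $1\times1$ head $W \in \mathbb{R}^{K\times C}$,
$A_c(i,j) = \sum_k W_{kc} F_{ijk}$ (no bias). Global average pooling and a
max-subtracted softmax give per-bin scores; the activation map of the
top-scoring bin is min–max normalized and thresholded at $\tau = 0.6$.
The largest **8-connected** component of the mask, scaled back to the
image frame, is the hand box. Two degenerate cases are handled explicitly:
a constant activation map yields an all-zero mask with a warning, and an
empty mask falls back to the full-image box, so branch 2 degrades to
branch 1 instead of failing.

Because pooling commutes with the linear projection, the class scores can
be computed either way; the tests assert this CAM-consistency identity.

### Part extraction (APEM)

The selected activation map is contrast-stretched,
$S = \mathrm{z}\!\left(\exp(\eta \, \mathrm{z}(A))\right)$ with $\eta = 4$
(z = min–max normalization), which preserves the location of every local
maximum while sharpening the gap between strong and weak responses.
Dense anchors with aspect ratios $\{2/3, 1, 3/2\}$ and scales
$\{128, 160, 224, 288, 384\}$ at stride 32 are defined on the native
576-pixel frame; anchors crossing the boundary are discarded (not
clipped). Each anchor is scored by the mean of $S$ inside it, computed in
O(1) per box with a summed-area table; greedy non-maximum suppression at
IoU 0.25 keeps diverse regions, of which the top $N = 4$ become part
crops (288×288 at native scale).

When the configured input size differs from 576 (the desk-scale
configuration uses 96 pixels), anchor scales and stride are rescaled
proportionally so the anchor geometry relative to the image is unchanged.

### Objectives

Each branch minimizes forward KL to the label distribution plus an L1
term summed over bins and averaged over the batch. (The source
publication's printed loss carries a leading minus sign on the KL term,
which would make it non-positive; it is implemented as standard
non-negative forward KL.) The raw and hand branches add a
temporal-ensembling consistency term: per-sample EMA targets
$S_t = \gamma S_{t-1} + (1-\gamma) \hat Y_t$, bias-corrected
$\bar Y = S_t/(1-\gamma^t)$, with $\gamma = 0.6$, weighted by the ramp
$T(t) = T_{\max} \exp(-5(1-t)^2)$, $t = \min(\text{epoch}/\text{ramp}, 1)$,
ramp length $= 0.8 \times$ epochs. The part branch, whose region proposals
move between epochs, has no temporal term. The total loss is
$L_{\text{raw}} + L_{\text{hand}} + \text{mean}_n L_{\text{part},n}$, and
the **hand branch** is the test-time prediction.

## Training without a deep-learning framework

The target environment ships no R tensor framework, so the package
implements the trainable part directly:

* a **fixed, seeded tiny backbone** — four blocks of 3×3 convolution
  (He initialization), ReLU, and 2×2 max-pooling, with channel widths
  8/16/32/32 and overall downsampling ×16 — written as vectorized base-R
  matrix operations and **frozen** after creation;
* a **frozen per-channel feature standardization** fitted on the training
  raw-image features, saturated at three standard deviations,
  $F_n = 3\tanh(z/3)$. The saturation matters: hand and part *crops* pass
  through the same standardization that was fitted on *raw* images, and
  their feature scale differs enough that unbounded z-scores destabilize
  the shared head (gradients are outer products of features);
* a single **trainable projection head** $W \in \mathbb{R}^{32\times240}$
  shared by all branches, trained by momentum SGD
  ($V \leftarrow \mu V + g$, $W \leftarrow W - \text{lr}\,V$,
  $\mu = 0.9$) with exact analytic gradients: softmax+KL gives $p - y$,
  the L1 term $p\,(s - \sum_i p_i s_i)$ with $s = \mathrm{sign}(p - y)$,
  and the temporal term $T(t)(p - \bar y)$. The gradients were verified
  against finite differences. The learning rate decays ×0.1 every 30
  epochs; the desk configuration uses lr = 0.1, chosen from a convergence
  check of the training loss (a linear head on bounded features tolerates
  and needs a far larger step than a deep network).

HOLM/APEM crops are *hard* attention: no gradient flows through crop
coordinates, which is also how the crops behave in the full-scale design.
Any function mapping an image to an $H\times W\times K$ array can replace
the tiny backbone; the rest of the pipeline is agnostic to it.

Training is bit-reproducible: the RNG state is stored in the model, a
resumed run continues the exact stream, and two same-seed runs produce
identical loss logs and weights.

## Synthetic phantoms

The generator draws grayscale hand phantoms: a bright hand rectangle at a
seeded offset on a noisy background, five phalange bars whose length is
**linear in age**, and carpal blobs whose count increments every 24
months — monotone, learnable age signals that loosely mimic how ossification
evidence accrues on real radiographs. Ages are uniform on [24, 228]
months; report strings alternate point style
(`"approximately %d years old"`, rounded years) and interval style
(`"%d–%d years old"` with an en dash, floor/floor+1 years), so the parser
and both label-centre rules are exercised. A regression of age on
measured bar length explains >90% of variance, so the signal is real but
not trivial. Limits of realism: no pose/rotation variation, no occlusion,
no device-dependent contrast, and the age cue is far simpler than true
ossification morphology — the phantoms validate machinery, not clinical
claims.

## Problem sizes

The package's study conditions — its own choices, sized for a desk-scale
CPU run — are 200 phantoms (160/20/20 train/val/test split), 96-pixel
inputs, 48-pixel part crops, 30 epochs, batch 32. On one CPU core this
trains in about four minutes and beats the predict-the-training-mean
baseline on held-out phantoms (46.1 vs 54.2 months MAE). Determinism is
additionally checked on a reduced 16-phantom, 3-epoch run of the same
code path to keep the test suite fast.

## Limitations

* The fixed tiny backbone has no learned spatial semantics, so absolute
  accuracy is far from clinical utility; the package demonstrates the
  label-distribution machinery, the attention pipeline and the training
  dynamics, not diagnostic performance.
* Part proposals are recomputed per epoch from the current head, so
  early-training proposals are near-random; the part branch mostly
  regularizes the shared head at desk scale.
* The parser covers the report grammar used by the generator plus common
  variants; free clinical text would need a broader grammar.
* Expectation decoding carries the truncation bias quantified above;
  argmax decoding avoids it at the cost of quantization to whole months.
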