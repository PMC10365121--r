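---
title: "Attention U-Nets for meningioma segmentation: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention U-Nets for meningioma segmentation: models, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attunet3d)
```

## The problem

Meningiomas are the most common primary brain tumor. On gadolinium-enhanced
T1-weighted MRI they appear as sharply circumscribed, strongly enhancing
extra-axial masses — but small ones are easily confused with other
contrast-enhancing structures, above all blood vessels. Automatic
segmentation supports growth monitoring at the outpatient clinic and
surgical planning, and it must work patient-wise: what matters clinically is
whether each tumor focus is *detected* at all, and how well the detected
focus is delineated.

`attunet3d` implements a modular family of volumetric encoder-decoder
networks for this task, a reversible preprocessing chain, training with
accumulated gradients, and a lesion-wise validation methodology (probability
threshold sweep, connected-component pairing, pooled cross-validation
estimates, volume-binned reporting). Because clinical cohorts of this kind
are access-restricted, the package ships a synthetic phantom generator so
that every stage is exercisable — and tested — end to end.

## Architectures

All models share a five-level 3D U-Net skeleton with per-voxel softmax
output over two classes. Four backbones are available:

* **unet** — the classic full-volume U-Net used as baseline: channel-doubling
  filters `[16, 32, 64, 128, 256]`, two 3x3x3 convolutions with batch
  normalisation and ReLU per level, max-pooling, trilinear upsampling and
  skip concatenation in the decoder.
* **agunet** — attention-gated U-Net: filters `[16, 32, 128, 256, 256]`,
  two 3x3x3 convolutions (bias, no normalisation) per level, 3x3x3
  transpose-convolution upsampling. Each skip connection is gated before
  concatenation: the coarser-scale features provide a gating signal, both
  are projected by 1x1x1 convolutions to an intermediate width
  `F_int = f_l / 2`, and a sigmoid coefficient map in (0, 1) multiplies the
  skip features. Gates suppress activations that are inconsistent with the
  coarse-scale context (e.g. vessel-like responses far from the predicted
  tumor region).
* **daunet** — dual-attention U-Net: a position-attention and a
  channel-attention module are computed once at the encoder bottleneck
  (computing them at every level is prohibitively expensive for the N^2
  position affinity). Each branch applies a 3x3x3 input convolution, its
  attention module with a residual connection through a learnable scale
  initialised at zero, spatial dropout (rate 0.5) on the raw attention
  maps, and a 3x3x3 output transform; the branch sum is the attention
  feature map (AFM).
* **dagunet** — dual-attention *guided* U-Net: the AFM is additionally
  resized to each decoder level, projected by a 3x3x3 convolution to the
  level's width, and concatenated into the decoder block.

Two toggles compose freely with every backbone:

* **multi-scale input (MS)** — the input volume is average-pooled (3x3x3
  kernel, stride 2) into a pyramid; at every encoder level the pooled copy
  is injected additively (broadcast over channels) and fused by a 3x3x3
  convolution, preserving raw-intensity detail that pooling of feature maps
  loses.
* **deep supervision (DS)** — auxiliary 1x1x1 softmax heads at every
  decoder level; the ground truth is recursively down-sampled
  (nearest-neighbour, so labels stay binary) to each head's grid and the
  total loss `L_Tot` is the uniform mean of the per-head losses.
  Averaging rather than summing keeps the loss magnitude comparable with
  DS on or off.

### Why these block internals

The conv-block composition of the published architecture family is not
fully specified by figure-level descriptions, so the internals above were
*calibrated*: the design space (convolutions per block, normalisation,
up/downsampling operator, gate widths, attention-block transforms) was
searched until the total trainable-parameter counts of the five reference
configurations reproduced the published figures at two-decimal precision
in millions:

```{r params}
for (cfg in list(arch_config("unet"),
                 arch_config("agunet"),
                 arch_config("agunet", multiscale = TRUE,
                             deep_supervision = TRUE),
                 arch_config("daunet", multiscale = TRUE,
                             deep_supervision = TRUE),
                 arch_config("dagunet", multiscale = TRUE,
                             deep_supervision = TRUE))) {
  cat(sprintf("%-8s MS=%d DS=%d  %.2f M\n", cfg$backbone, cfg$multiscale,
              cfg$deep_supervision, count_parameters(cfg) / 1e6))
}
```

Three consequences of the calibration are worth flagging. The gating
signal enters each attention gate at the coarser scale (before
upsampling), with the projected gate resized to the skip grid — gating
from the post-upsampling features would change the gate widths and miss
the published count. The multi-scale injection is additive rather than a
1-channel concatenation, again fixed by the counts. And the baseline
full-volume U-Net uses the channel-doubling filter scheme of its original
description, not the attention family's `[16, 32, 128, 256, 256]` layout,
which cannot reach its published size under any block variant we
enumerated.

The parameter inventory is assembled symbolically (no tensors are
allocated), so full-size graphs build in milliseconds; the same inventory
drives weight initialisation (He/variance-scaling with a fixed seed) and
the executable forward/backward pass used at training scale.

## Losses

The main loss is the class-average soft Dice loss excluding the
background, with smoothing `eps = 1e-5` in numerator and denominator. The
Focal Tversky loss is available as an alternative: per foreground class
`TI = (TP + eps) / (TP + 0.7 FN + 0.3 FP + eps)` on soft counts and loss
`(1 - TI)^(1/gamma)` with `gamma = 2`, the exponent convention of the
loss's original formulation (so `gamma = 1` recovers the plain Tversky
loss). The alpha/beta asymmetry deliberately penalises false negatives
more than false positives, favouring recall.

## Training

Adam (initial learning rate `1e-3`), micro-batches of 2 with accumulated
gradients: `n` micro-batch gradients are evaluated at identical weights,
averaged, and applied in a single update, so the applied gradient equals
the gradient of the mean loss over the effective batch
(`batch_size * accum_steps`; 2 x 16 = 32 in the reference configuration).
Averaging rather than summing keeps the effective learning rate invariant
to the accumulation count. This equivalence is exact for norm-free
networks and is verified numerically in the test suite; with batch
normalisation the statistics are computed per micro-batch, a standard and
documented deviation from exact large-batch equivalence.

Early stopping monitors the validation selection loss — `L_Tot` by
default, or the top-level head's loss for the "Top" model-selection
variant — and halts after 30 epochs (configurable) without improvement,
returning the best checkpoint.

Two implementation details stabilise small-cohort training. The effective
gradient is clipped to a global norm of 1.0 before each update: with the
background-excluding Dice loss, batches whose tumors are nearly lost
produce disproportionate gradients, and without clipping the optimiser can
drive the network into the all-background local minimum from which the
saturated softmax cannot recover (we observed exactly this collapse in
unclipped runs). And validation is always computed without augmentation.

Training-time augmentation applies five transforms, each with independent
probability 0.5: horizontal and vertical in-plane flips, in-plane rotation
in [-20, 20] degrees, translation up to 10% of each axis, and in-plane
zoom in [80, 120]%. Image and label receive the identical transform
(order-1 vs nearest-neighbour sampling, zero fill).

## Preprocessing and its inverse

Four steps: resampling to isotropic 1 mm spacing (order-1 splines for
images, nearest for labels), tight cropping around the head, resizing to
the 128x128x144 network grid, min-max normalisation to [0, 1]. "Tight
around the head" is made operational as: global Otsu threshold, largest
26-connected component, morphological closing with a 3x3x3 cube, bounding
box — a parameter-free rule. The record of every step suffices to invert
the geometry exactly: probabilities are resized back into the crop box,
embedded at zero outside it (no evidence can exist outside the head), and
resampled to the native grid. All resampling uses half-pixel-centre
alignment so the restoration is the exact adjoint mapping of the forward
chain; a preprocess-restore round trip on tumor masks of at least 1 ml at
1 mm native spacing keeps Dice at 0.95 or higher (tested). The 144-voxel
axis is the slice axis by convention and configurable.

## The phantom generator

The generator emulates the statistical structure the networks must cope
with, not MRI physics:

* **Geometry** — nested head/scalp and brain ellipsoids; piecewise-constant
  tissue intensities (background 0, scalp 60, brain 100, tumor 200,
  vessel 200, arbitrary units) with small per-tissue texture noise.
* **Tumors** — ellipsoidal instances with anisotropy ratios in
  [0.75, 1.3]. Volumes follow a log-normal truncated to [0.07, 167.99] ml
  whose parameters are moment-matched numerically so the truncated mean
  and SD reproduce the study cohort (18.33 +/- 27.20 ml); the closed-form
  truncated moments make calibration fast and the achieved mean is within
  1% of target. The truncated log-normal is an assumption — only mean, SD
  and range of the real cohort are public — chosen for its right-skewed
  positive support. Placement is extra-axial: centres sit in a shell of
  +/-10% of the brain radius around the brain surface along a random
  direction; tumors too large for the shell shift inward along the
  placement direction, mimicking how large lesions indent the brain.
* **Distractors** — bright vessel-like tubes (random-walk polylines,
  radius 2 mm, intensity equal to tumor) inside the brain, the main
  false-positive source in the real task.
* **Artifacts** — a smooth multiplicative bias field (coarse 4^3 random
  grid upsampled trilinearly, amplitude 20%) emulating intensity
  inhomogeneity, plus additive Gaussian noise (sigma 4). Labels stay
  noise-free.

The default grid is 64x64x72 at 2 mm (a full-scale 256x256x192 at 1 mm is
one configuration away). Cohorts are reproducible from a single seed, and
five-fold splits are volume-balanced by sorting cases on total tumor
volume and dealing them serpentine-wise, so each fold sees a similar
volume distribution.

What passing tests on phantoms does *not* show: robustness to real
anatomy, scanner variation, partial-volume effects at real tumor
boundaries, non-enhancing or calcified lesions, or the true difficulty of
sub-3-ml detection. The phantoms establish that the machinery — geometry,
losses, optimisation, instance pairing — is correct, not that the models
reach clinical performance.

## Validation methodology

Probability maps restored to the native frame are swept over ten
thresholds PT in {0.1, ..., 1.0}. At each PT, predicted and ground-truth
instances are maximal 26-connected components; they are paired greedily by
descending voxel overlap, one-to-one, any overlap qualifying as a
detection (on well-separated lesion configurations this greedy matching
attains the exhaustive optimum, which the suite checks by brute force).
Per patient we report the global Dice and the true-positive Dice (against
the union of TP-paired components only, so a detached false positive
lowers Dice but not Dice-TP); per fold, recall / precision / F1 from the
summed instance counts, with empty denominators reported as missing rather
than zero. Pooled cross-validation estimates are fold-size-weighted means
and standard deviations of the fold-level metrics. The operating PT
maximises F1, ties broken toward higher mean Dice, then toward the lower
threshold. Volume-binned reports use ten equally populated bins (by
ground-truth volume) and a separate split at the 3 ml clinical cutoff.

## Numerical choices and problem sizes

The package carries its own reverse-mode tape over dense arrays with
Rcpp kernels for the volumetric primitives (direct shifted-axpy
convolutions, which outperform im2col+GEMM at the small channel counts
used in testing; exact adjoints for pooling and trilinear resizing).
Gradients of every backbone are verified against central finite
differences — evaluated at weights jittered away from zero, since with
zero-initialised biases many ReLU arguments sit exactly on the kink where
finite differences are ill-defined while the analytic value is a valid
subgradient.

Tests and examples run at deliberately small problem sizes chosen to keep
the full suite fast while still exercising every code path: phantoms of
16^3-96^3 voxels, networks of 2-3 levels with 2-16 filters, cohorts of
4-40 cases. The end-to-end check trains a 3-level AGUNet-MS-DS (filters
[4, 8, 16]) on 40 phantoms at 48^3 and expects a held-out soft Dice of at
least 0.70; full-size configurations are validated structurally (graph
shapes and parameter counts) rather than by training.

## Known limitations

* No MRI physics in the phantoms (no k-space, sequences, skull detail) and
  no edema/FLAIR modelling.
* Training at the full 128x128x144 scale is out of reach of a plain-R
  tape on CPU; the executable path is intended for method verification
  and small-scale experiments.
* Batch-norm statistics update per micro-batch under gradient
  accumulation (the standard caveat).
* The greedy instance pairing can differ from the optimal assignment on
  adversarial overlap configurations (a prediction bridging two ground
  truth foci that are each other's only partners); on realistic
  well-separated lesions it is optimal, and the suite tests exactly that
  regime.
* On the synthetic fixture, deep supervision accelerates early training
  markedly but does not reliably reduce the number of epochs needed to
  cross a fixed high training-Dice mark: the crossing statistic is
  dominated by late-phase optimisation noise on the easy phantom task, and
  the suite's directional check of that crossing documents this honestly
  rather than asserting around it.
* Surface-distance metrics (HD95, ASSD) and significance testing between
  experiments are out of scope.
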