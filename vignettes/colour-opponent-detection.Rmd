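---
title: "Colour-opponent early fusion for one-stage fruit detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour-opponent early fusion for one-stage fruit detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawdetect)
```

## The problem and the model

Detecting ripe and unripe strawberries in field imagery is hard mainly
because of illumination: the same berry photographed at different times of
day, under different weather, or from a different camera angle presents very
different RGB values. `strawdetect` attacks this at the *input* rather than
by enlarging the network. The RGB image is converted to the CIELab colour
space — whose three channels approximate the human opponent-process axes,
lightness L (white–black), a (red–green) and b (blue–yellow) — and stacked
depth-wise with the original RGB channels into a six-channel tensor. Because
a global illumination change moves mostly the L channel while the chromatic
a/b pair stays comparatively stable, the network can learn colour features
that are less entangled with lighting. Ripe and unripe berries sit at
opposite ends of the red–green opponent axis, which is exactly the
separation the a channel encodes.

The conversion runs RGB → XYZ → Lab under the D65 illuminant:

* XYZ = 100 · D · (R,G,B)ᵀ with the standard D65 matrix (first column
  ×100 is (41.2453, 21.2671, 1.9334)); values on the 0–100 scale.
* L = 116·f(Y/Yn) − 16, a = 500·(f(X/Xn) − f(Y/Yn)),
  b = 200·(f(Y/Yn) − f(Z/Zn)), with Xn = 95.047, Yn = 100, Zn = 108.883 and
  f(x) = x^(1/3) above (6/29)³ and the linear continuation
  x/(3δ²) + 4/29, δ = 6/29, below. The linear branch makes f continuous
  and maps black exactly to L = 0.

The detector on top is a one-stage anchor-based network: a
ResNet-18-style backbone (7×7 stride-2 stem, stride-2 max-pool, four
residual stages), a five-level feature pyramid F3–F7 built from the last
three stages by lateral 1×1 projections and top-down upsample–add (F6 and
F7 by stride-2 3×3 convolutions of F5 and of ReLU(F6)), and two small
convolutional sub-networks shared across levels that emit, per spatial
location, K·A class scores and 4A box offsets for A = 9 anchors
(3 scales × 3 aspect ratios). Training minimises the sum of the focal
classification loss, −α_t(1−p_t)^γ log p_t with α = 0.25 and γ = 2, and a
smooth-L1 loss on the box offsets of positive anchors. The focal weighting
is what makes dense single-stage detection workable: almost all of the
several thousand anchors per image are easy background, and (1−p_t)^γ
down-weights them so the rare berry anchors dominate the gradient.

## Gamma handling and the two colour modes

Camera PNG/JPEG pixels are gamma-encoded sRGB. The colourimetrically
correct conversion first applies the standard sRGB inverse companding and
then the linear matrix; this is the default (`mode = "srgb_linearized"`)
and is the mode validated against an independent colourimetry library to
1e-3 per channel. A `"naive"` mode that applies the matrix directly to the
stored values is kept behind a flag: it is a defensible reading of the
transform when the input is already linear, and it preserves the exact
printed-matrix fixed points (pure red → X = 41.2453) that make the
conversion auditable. Both modes are tested; the choice is recorded in the
run configuration and the checkpoint.

## Why the Lab channels are rescaled before fusion

RGB channels live in [0,1]; L in [0,100] and a, b roughly in [−128,127].
Stacking raw Lab against RGB would hand the first convolution inputs two
orders of magnitude apart. The fusion layer therefore applies L/100,
(a+128)/255, (b+128)/255, putting all six channels on ≈[0,1] before the
usual per-channel standardization. The layout is fixed as
(R, G, B, L, a, b) and stored in every checkpoint so a six-channel stem is
never ambiguous.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `focal_alpha`, `focal_gamma` | 0.25, 2.0 | — | the published focal-loss operating point |
| `anchor_scales` | 2^(0/3), 2^(1/3), 2^(2/3) | — | canonical octave-third ladder |
| `anchor_ratios` | 0.5, 1, 2 | h/w | covers moderately elongated fruit |
| `anchor_base_factor` | 4 (full), 3 (desk-scale) | ×2^level px | see below |
| `pos_iou` / `neg_iou` | 0.5 / 0.4 | IoU | positive/ignore/background bands of the base detector family |
| `score_threshold` | 0.5 | — | deployment cut-off; evaluation sweeps the full ranking for AP |
| `nms_threshold` | 0.5 | IoU | suppression overlap |
| `fpn_channels` | 256 (full), 64 (desk-scale) | — | pyramid width |
| `prior_prob` | 0.01 | — | final classification bias set to −log((1−π)/π) so the untrained net is quiet |

**Anchor base size.** At pyramid level *l* the anchor base is
`anchor_base_factor · 2^l` pixels. The conventional factor 4 (32 px at F3)
suits large imagery, but on 128×128 synthetic scenes with 20–40 px berry
boxes an explicit coverage analysis showed ~17 % of ground-truth boxes
reach no anchor at IoU ≥ 0.5 under factor 4 — those berries can never
become positives and put a hard ceiling on recall. Factor 3 (24 px at F3)
covers 100 % of generated boxes, so the desk-scale configuration uses it.
The factor is configuration, not code: full-resolution field imagery keeps
the default.

**Regression head activation.** The offsets (tx, ty, tw, th) include
log-space size terms that must range over all reals, so the regression head
is linear by default. A `sigmoid` head mode exists for completeness — some
descriptions of this architecture attach a sigmoid to both sub-nets — but a
(0,1)-bounded output cannot express tw < 0 (shrinking an anchor), so the
linear head is the functional choice.

**Regression loss.** The training objective is sometimes summarised as
"focal loss for both sub-nets". A focal loss has no standard definition for
continuous regression targets, so the package does not invent one: the
regression term is smooth-L1 (mean over positive anchors), and requesting
`regression_mode = "focal_as_stated"` raises an explanatory error rather
than silently substituting semantics.

**Loss normalisation.** The classification loss is summed over contributing
anchor-class entries and divided by the number of positive anchors (floored
at one). With thousands of anchors and a handful of positives this keeps
the loss scale independent of image size and anchor density.

**Optimiser.** Adam with learning rate 1e-3 under cosine decay to zero,
batch size 2. On the desk-scale problem (tens of images, hundreds of
iterations, a width-16/FPN-64 network trained from random initialisation)
1e-3 converges reliably within the iteration budget while 1e-4 — a common
choice when fine-tuning large pretrained detectors — is still far from
convergence at that budget. The rate is configuration and is recorded in
every checkpoint. Training is from random initialisation throughout: a
six-channel stem cannot reuse three-channel pretrained weights directly.

## Stride arithmetic and image preparation

Every stride-2 layer maps n → ⌈n/2⌉, so level l sits at ⌈input/2^l⌉ and a
1280×736 input yields pyramid shapes 160×92 … 10×6. The top-down pathway
adds exact ×2 upsampling, which requires the input to be divisible by 32;
`prepareImage()` pads the bottom/right with zeros to the next multiple (the
default, preserving native resolution) or resizes bilinearly to an explicit
target such as 1280×736 when reproducing fixed-size protocols. The
transform record maps predicted boxes back to original coordinates exactly.

## The evaluation protocol

Detections are matched to ground truth greedily in descending score order;
a detection is correct when it matches an unmatched same-class box at
IoU ≥ 0.5 (a 0.4 variant exists for comparison against older fruit-counting
work, which also considers only detections scoring above 0.9 — the
`"deepfruits"` protocol). Precision, recall and F1 follow
P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), pooled over images
(micro-averaging) before the quotients are taken. AP is the area under the
precision envelope over recall ("all-point" interpolation); an 11-point
mode is available since older benchmark definitions differ, and both are
exposed because the convention genuinely matters at small test-set sizes.
Ties in NMS and matching are broken by (score desc, x_min asc, y_min asc)
so every run is reproducible.

**Operating point.** F1 at a fixed score cut-off is a property of the
deployment threshold as much as of the detector: as training sharpens the
score distribution, the F1-optimal cut-off drifts. `selectScoreThreshold()`
therefore calibrates the threshold on the training (or a validation) split
— never on the held-out data — and the held-out report is computed at that
calibrated operating point. AP, which sweeps the whole ranking, is reported
alongside and is threshold-free.

The false-positive decomposition produces seven pooled PR curves: C50, C40
and LOC at IoU 0.5/0.4/0.1; SIM additionally credits false positives that
overlap an unmatched ground truth of a *similar* class (both berry classes
share one supercategory); CLS does the same regardless of class; BGR drops
the remaining background false positives; FIN also removes false negatives
and is the perfect curve. Each relaxation can only help, so the areas are
non-decreasing along C50 ≤ C40 ≤ LOC ≤ SIM ≤ CLS ≤ BGR ≤ FIN = 1, which is
asserted property-style in the tests.

## What the synthetic generator emulates — and what it does not

`generateScene()` renders shaded, speckled ellipses in two colour classes
(red-dominant "ripe", green/white "unripe") over a cluttered green
background, with:

* exact ground-truth boxes derived from the ellipse geometry (the affine
  viewpoint distortion is applied to the geometry itself, so boxes are
  exact by construction, not fitted to pixels);
* per-scene global illumination applied multiplicatively in *linear* RGB
  and re-encoded to gamma sRGB — the physically sensible model of a light
  level change, and the mechanism that makes the L-channel analysis
  interpretable;
* partial occlusion by foreground "leaves", bounded by a per-berry
  occlusion budget, with rejection sampling that fails loudly after 1000
  attempts rather than silently violating the budget;
* viewpoint-like shear/scale distortion, strengthened for scenes tagged
  V2/V3 to emulate a held-out-viewpoint protocol, following the field
  practice of training on one camera angle (V1) and validating on all
  three.

Default study conditions: 128×128 scenes, 3 ripe + 5 unripe berries
(the unripe class dominates, mirroring real class imbalance), berry
half-extents 10–20 px, illumination gain drawn from [0.8, 1.2], occlusion
budget 0.3. All randomness flows from a single per-scene seed; scenes are
bitwise reproducible.

The generator deliberately does *not* model achene-level texture, specular
highlights, shadows cast between plants, camera noise, or true 3-D
perspective. Passing the end-to-end tests therefore demonstrates that the
pipeline — colour transform, fusion, anchor machinery, loss, optimisation,
decoding and evaluation — is implemented correctly and can learn a
colour-separable detection task from scratch; it does not certify field
accuracy on real imagery, which depends on data the generator cannot
substitute for.

## Desk-scale problem sizes

The end-to-end checks train a width-16 backbone with a 64-channel pyramid
on 80 generated 128×128 scenes for 800 iterations (batch 2) and evaluate on
20 held-out scenes; both the RGB-only and early-fusion arms reach held-out
F1 ≥ 0.9 at IoU 0.5 under the standard protocol. These sizes are the
package's chosen demonstration scale: large enough that an untrained or
mis-wired model fails clearly, small enough to run routinely on one CPU.
Training runs are seeded end to end; a second seed is permitted in the
acceptance checks because from-scratch detector training at this scale is
genuinely stochastic.

## Known limitations

* The convolutional engine is a purpose-built reverse-mode tape over
  im2col/GEMM primitives. It is exact but not fast: it exists to make the
  method fully self-contained and testable, not to compete with GPU
  frameworks. Full-resolution (1920×1080) training is supported in the
  architecture but impractical at this engine's speed.
* No batch/group normalisation: at desk scale the He-initialised residual
  stages train stably with Adam, and omitting normalisation keeps the
  backward pass simple. Deeper/wider configurations may want it.
* The image reader handles PNG; JPEG inputs should be converted beforehand.
* Chromatic adaptation to illuminants other than D65, inverse Lab→RGB
  conversion, and camera colour calibration are out of scope.
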