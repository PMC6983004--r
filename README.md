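# strawdetect

Colour-opponent early-fusion detection of ripe and unripe fruit in field
imagery, in pure R (with a small Rcpp/Armadillo compute core).

Outdoor fruit detection is dominated by illumination: the same berry looks
radically different in RGB across times of day, weather and camera angles.
`strawdetect` converts each RGB image to the CIELab opponent colour space
under the D65 illuminant —

```
XYZ = 100 · D · (R,G,B)ᵀ            (D the standard D65 matrix)
L = 116·f(Y/Yn) − 16
a = 500·(f(X/Xn) − f(Y/Yn))         f(x) = x^(1/3)  above (6/29)³,
b = 200·(f(Y/Yn) − f(Z/Zn))                x/(3δ²) + 4/29 below, δ = 6/29
```

— and stacks it depth-wise with the RGB channels into a six-channel tensor
(R, G, B, L, a, b). A light-level change moves mostly L, while ripe and
unripe fruit separate along the red–green opponent axis a. This fused tensor
feeds a one-stage anchor-based detector: ResNet-18-style backbone, five-level
feature pyramid (F3–F7), shared classification/regression sub-nets with
A = 9 anchors per location, trained with the focal loss
(−α_t(1−p_t)^γ log p_t, α = 0.25, γ = 2) plus smooth-L1 box regression.

The package also implements the complete evaluation protocol — greedy IoU
matching, P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), average precision,
NMS, per-viewpoint breakdowns and the seven-curve false-positive
decomposition (C50, C40, LOC, SIM, CLS, BGR, FIN) — plus COCO-style
annotation IO and a deterministic synthetic scene generator so the entire
pipeline trains and validates on one CPU.

## Worked example

```r
library(strawdetect)

# 1. generate annotated synthetic scenes (deterministic per seed)
spec  <- sceneSpec()                        # 128x128, 3 ripe + 5 unripe
train <- lapply(1:80, function(i) generateScene(spec, seed = 1000 + i))
test  <- lapply(1:20, function(i) generateScene(spec, seed = 2000 + i))

# 2. train the early-fusion arm of a desk-scale detector
cfg <- runConfig(fusion = "early_fusion",
                 model = modelConfig(input_channels = 6, backbone_width = 16,
                                     fpn_channels = 64, anchor_base_factor = 3),
                 lr = 1e-3, iterations = 800, batch_size = 2, seed = 42)
model <- trainDetector(train, cfg)

# 3. calibrate the operating point on training scenes, evaluate held out
thr <- selectScoreThreshold(model, train[1:30])$threshold
evaluateDetector(model, test, protocol = "standard", score_threshold = thr)
```

On this run (about five minutes on one CPU) the calibrated threshold is
0.65 and the report prints:

```
EvalReport (standard protocol: IoU 0.50, score >= 0.65)
  view_group  class  TP FP FN      P     R     F1     AP
1    overall   ripe  54  5  6 0.9153 0.900 0.9076 0.8956
2    overall unripe  94  9  6 0.9126 0.940 0.9261 0.9293
3    overall   mean 148 14 12 0.9136 0.925 0.9193 0.9124
```

i.e. the six-channel detector recovers 92.5% of planted berries at IoU 0.5
with 91.4% precision. Held-out F1 varies by a few points across training
seeds; the detector is trained from random initialisation. `detectScene()`
returns per-image detections (box, class, score); `detectImages()` batches
over PNG files and writes COCO-results JSON; `fpAnalysis()` decomposes the
remaining errors into localisation / classification / background components.

A thin command-line front end with subcommands `make-synthetic`, `train`,
`detect`, `evaluate` and `convert-colour` ships in
`inst/scripts/fruittool.R`.

See the vignette (`vignettes/colour-opponent-detection.Rmd`) for the model,
its parameters, the numerical choices, and what the synthetic benchmark does
and does not demonstrate.

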