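---
title: "VesselFuse: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VesselFuse: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
segmentation model and its assumptions, the parameters that matter and why
they hold their defaults, what the phantom generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The segmentation model

A fundus photograph shows dark vessels on a bright, unevenly illuminated
background. The vessel cross-section is an inverted Gaussian — darkest at
the centerline — and vessel width spans roughly 1-6 pixels at typical
resolutions, with thin vessels both the hardest and the clinically most
informative targets. Three enhancement channels attack different parts of
this problem:

* **Closing-based background removal** (channel 1). The grayscale closing
  with a disc of radius 11 px removes every dark structure narrower than
  the disc, i.e. all vessels, leaving a background estimate. The transform
  `g = 255 - (I_close - I) + mean(I_close)`, min-max rescaled to 0-255,
  keeps all vessel-scale detail while flattening illumination and the
  bright optic disc. Radius 11 must exceed the widest expected vessel
  radius; it is configurable per channel.
* **Matched filtering** (channels 2 and 3). The canonical template is
  `K(u, v) = -exp(-u^2 / (2 s^2))` on the support `|u| <= 3s`,
  `|v| <= l/2` — an inverted Gaussian ridge of length `l`. The template is
  rotated to `n` orientations spaced `pi/n` apart, each rotated copy is
  made exactly zero-mean over its support, and the pixel response is the
  maximum correlation over orientations. Zero-mean templates return zero
  on locally constant background, so only line-like structure responds.
  The large scale (`l = 10.8`, `s = 1.9`, 8 orientations) targets thick
  vessels; the small scale (`l = 5`, `s = 0.1`, 18 orientations) targets
  the thinnest ones, with more orientations because narrow templates are
  more direction-selective.
* **Inverted double black-hat.** The classical black-hat
  `B = closing(f) - f` highlights dark detail smaller than the disc. The
  variant used here, `g = 255 - (f - 2B)` clipped to 0-255, inverts the
  image while pushing black-hat detail twice as far, deepening the
  vessel/background separation of the filtered maps before they reach the
  network.

Each channel feeds its own encoder-decoder network; the three outputs are
binarized and fused with a pixelwise OR. OR fusion is deliberately
greedy: a vessel missed by two channels but found by one survives, which
is what reconnects fragmented thin vessels — at the price of collecting
every channel's false positives, which the 25-pixel component pruning then
removes.

### Decisions the sources left open

* **Direction aggregation** of the filter bank is the pixelwise maximum
  over orientations, the standard choice for Gaussian matched filters.
* **The small-scale support problem.** With `s = 0.1` the nominal
  cross-section `|u| <= 3s = 0.3` px contains no nonzero integer offset;
  mean subtraction would annihilate the kernel. The across-line half-width
  is therefore floored at one pixel (`|u| <= max(3s, 1)`), preserving a
  3-pixel-wide dark-line template; a message is logged whenever the floor
  activates.
* **Rotation sampling** maps each integer pixel of a common bounding box
  *back* into the canonical frame by the inverse rotation (no holes),
  rather than forward-rotating and rounding support points.
* **Polarity through the pipeline.** After preprocessing, vessels are
  dark; the matched-filter response makes them bright; the inverted
  double black-hat makes them dark again. All three channels therefore
  hand the network dark-vessel images, and the network's sigmoid output
  is bright on vessels. This was validated on phantoms (vessel/background
  mean separation at every stage, response AUC > 0.8 as a property test).
* **Border handling** is mirror reflection everywhere a window leaves the
  frame (correlation, morphology, local-mean thresholding), which avoids
  spurious edge responses from zero padding.

## The network and its training objective

The architecture is fully convolutional: five encoder double-convolution
blocks (widths 64-128-256-512-512) with 2x2 max pooling, four decoder
blocks (256-128-64-64) of bilinear upsampling + skip concatenation +
double convolution, and a 1x1 sigmoid head. Every convolution is 3x3 with
padding 1, bias, batch normalization and a leaky rectifier (slope 0.01),
so any input side divisible by 16 is accepted and spatial dimensions are
preserved. A double-convolution block with widths `C1 -> C2` holds
`9(C1+C2)C2 + 6C2` learnable terms; the full reference model holds
13,394,177. `countParameters()` derives this ledger from the actual
arrays, never from a formula, so it doubles as a wiring audit.

The loss is `L_dice + 0.5 * L_r`. The soft Dice term optimizes overlap
directly and is insensitive to the overwhelming background class. The
cross-entropy term weights the positive and negative summands by
`1 - TP/Np` and `1 - TN/Nn` — the false discovery rates of the current
hard (0.5-thresholded) predictions, recomputed per batch with no gradient
through the weights: a class whose predictions are already clean
contributes nothing, a noisy class is pushed hard. Decisions made here:
the sum is divided by the pixel count so magnitudes are
resolution-independent (this only rescales the effective learning rate);
`epsilon = 1e-7` clamps the logarithms and smooths the Dice denominator;
an unpredicted class gets weight 1 (its limit from the formula).

Training is SGD (momentum 0.9, no weight decay) for 30 epochs under the
staged schedule 0.01 / 0.001 / 0.0001, each stage one third of the run;
the first stage covers epochs 1-10 at the default length (the printed
first branch of the schedule contradicts its other branches; it is read
as "epoch <= 10", consistent with 0.01 being the initial rate). For runs
shorter than 30 epochs the three stages scale proportionally. The
training set is expanded 4x (original + horizontal flip + vertical flip +
180-degree rotation, labels transformed jointly). By default 10% of the
(augmented) pairs are held out and the epoch with the best held-out hard
Dice supplies the final weights; `valFraction = 0` disables this for
schedule-faithful runs. Per-batch weight recomputation (rather than per
image or per dataset) was chosen because it tracks the optimizer state;
the choice is isolated in one helper.

The engine is a compact CPU implementation: compiled im2col + BLAS GEMM
convolutions, fused batch-norm/leaky-ReLU kernels, argmax-cached pooling,
sparse-matrix bilinear upsampling, and analytic backpropagation (verified
against finite differences and a plain-R reference in the test suite).
Weights are Kaiming-uniform, batch norm starts at scale 1 / shift 0, and
network inputs are scaled to `[0, 1]`. Runs are bit-reproducible for a
fixed seed on a fixed BLAS.

## Binarization, fusion, pruning

The local threshold is `T = -b + mean` over a `(2m+1) x (2n+1)` window
(default 31x31), vessel iff the value exceeds `T`. The default offset is
`b = -15` *on the 0-255 scale*, i.e. the threshold sits 15 gray levels
above the local mean. The sign matters: with a positive `b` the threshold
sits *below* the local mean, and any window of near-constant background
(local mean ~ 0 on a probability map) classifies every pixel — including
pure background — as vessel. A negative offset keeps flat regions
background while vessel ridges, which sit well above their local mean,
still cross the threshold; probability maps are multiplied by 255 before
thresholding so the offset's scale matches the image case. Binarization
happens in the network frame; masks are restored to native dimensions by
nearest neighbor (so they stay binary), and the 25-pixel pruning rule is
applied at native scale, where the printed threshold is meaningful.

## Evaluation suite

Se, Sp and ACC are standard; the AUC reported here is `(Se + Sp)/2` —
balanced accuracy computed from the same confusion counts, *not* a
ROC-curve area (property-tested as an identity). The Matthews correlation
uses the standard numerator `TP*TN - FP*FN`; a non-standard variant with
numerator `TP*TN - TP*FN` appears in some reports and is available behind
`printedVariant = TRUE` for auditing. CAL multiplies Connectivity
(agreement of 8-connected component counts, normalized by the
ground-truth vessel count), Area (overlap of radius-2 disc dilations) and
Length (skeleton agreement within radius-2 dilations); skeletons come
from iterative two-subiteration homotopic thinning, dilations use exact
Euclidean discs on the integer lattice. Evaluation is restricted to the
FOV mask when one is available; both conventions are supported since
published figures rarely state which was used.

## The phantom generator

`generatePhantom()` emulates the statistics the pipeline depends on: a
bright background (~200) with a smooth illumination field, an optional
bright optic-disc blob, 1-6 px vessels radiating from near the disc along
bounded-curvature quadratic curves, an inverted-Gaussian cross-section
(`sigma_w = width/2`, dip 40-80 gray levels), additive Gaussian noise
(sigma 5), a circular FOV at 0.48 of the frame side, and a vessel
prevalence of a few percent — the class imbalance the loss is built for.
Ground truth is derived from the analytic distance to the centerline, not
by re-thresholding the rendering, so labels are exact. The green plane
carries the strongest vessel contrast, as in real photographs.

What phantoms do *not* emulate: branching trees with realistic
bifurcation statistics, central vessel reflexes, pathology (lesions,
exudates, hemorrhages), camera vignetting and JPEG artifacts, and
inter-image illumination variability. Passing the synthetic suite
therefore demonstrates that the pipeline's machinery — enhancement
polarity, learning, fusion, metrics — is correct and recovers curvilinear
structure under the stated noise model; it does not certify benchmark
performance on real fundus images, which requires the real datasets.

## Problem sizes and reproducibility of the checks

The test suite trains reduced-width networks (`base = 2`, i.e. encoder
widths 2-4-8-16-16) on 128x128 phantoms for 15 epochs — widths are the
only thing scaled down; wiring, losses, schedule and augmentation are the
reference configuration. These sizes were chosen so the whole synthetic
recovery (three channels, 40 training phantoms, 10 held-out) completes in
minutes on one CPU core while still exercising every code path; held-out
fused Dice clears the 0.7 property threshold. The
architecture ledger and all printed-table identities run at full
reference width, which costs only memory for the parameter arrays.

## Known limitations

* Training at the full 576x576 / width-64 configuration is possible but
  slow on a single CPU core; the engine is written for correctness and
  reproducibility first.
* GIF and PPM sources are not decoded (no decoder in the underlying I/O
  library); PNG, TIFF and JPEG are supported.
* The FOV recipe (blur, Otsu, fill, largest component, erode 3 px) is one
  reasonable realization of "morphological algorithms and threshold"; on
  unusual montages the erosion margin may need adjustment.
* The adaptive threshold assumes probability maps are locally bimodal;
  for very dense vasculature a 31x31 window may straddle mostly-vessel
  regions and the offset would need retuning.
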