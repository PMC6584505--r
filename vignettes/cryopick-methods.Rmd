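---
title: "cryopick: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cryopick: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cryopick localizes single particles in cryo-EM micrographs with a
single-shot, grid-regression convolutional detector. This vignette explains
the model and its assumptions, the synthetic-micrograph generator used for
training and validation, the numerical choices baked into the
implementation, and what the shipped tests do and do not demonstrate.

## The detection model

A micrograph (or an overlapping patch of it) is downscaled to a square
network input of side $L$ (default 1024, reduced configuration 256) and
standardized per image to zero mean and unit SD. Five 2×2 max-pooling
layers downsample by a factor of 32, so predictions live on an
$S \times S$ grid with $S = L/32$; each grid cell is responsible for
particles whose box center falls inside it, and can detect at most one
particle. Per cell the detector outputs six channels: the center offsets
$\hat x, \hat y \in (0,1)$ within the cell, the box sides
$\hat w, \hat h$ relative to a single reference (anchor) box, an
objectness confidence $\hat C \in (0,1)$, and a class score that is
redundant for a single particle species and ignored at decode time (it is
kept so the detection head has its full six-filter width).

The feature extractor is 21 convolutions (3×3 and 1×1, same padding), each
followed by batch normalization and a leaky ReLU with slope $\alpha = 0.1$,
with the filter schedule 32–1024 of the classic single-shot detector this
architecture follows. A passthrough connection takes the activated output
of layer 13 (stride 16), reshapes it space-to-depth by 2 and concatenates
it channel-wise into the input of layer 21, preserving fine spatial detail
at the detection resolution. Detection is dropout (rate 0.2, training only)
followed by a single 1×1 convolution with 6 filters.

Because only one particle species is picked at a time, a single anchor is
used; its side length is the user's particle box size expressed in
network-input pixels. Output activations are not dictated by the loss
alone, so the package adopts the convention of the ancestor detector
family: logistic on offsets, confidence and class score; exponential on the
size channels (decoded size $=$ anchor $\cdot e^{\text{raw}}$). This keeps
offsets inside their cell and sizes positive, which the square-root loss
term presumes. Whether sizes should be stored relative to the anchor or to
the image is genuinely open; relative-to-anchor makes the size channels
dimensionless with a well-scaled target of about 1, and is what the single
reference box suggests.

## The loss

With $1_i^{obj}$ indicating cells holding a box center,

$$L = \lambda_{coord}\sum_i 1_i^{obj}\left[(x_i-\hat x_i)^2 +
(y_i-\hat y_i)^2\right]
+ \lambda_{coord}\sum_i 1_i^{obj}\left[(\sqrt{w_i}-\sqrt{\hat w_i})^2 +
(\sqrt{h_i}-\sqrt{\hat h_i})^2\right]$$
$$+ \lambda_{obj}\sum_i 1_i^{obj}(C_i-\hat C_i)^2
+ \lambda_{noobj}\sum_i 1_i^{noobj}(C_i-\hat C_i)^2$$

summed over all $S^2$ cells, with confidence targets $C_i = 1$ at object
cells and 0 elsewhere (no IOU reweighting — one anchor, one class). The
class channel is trained toward 1/0 with the same
$\lambda_{obj}/\lambda_{noobj}$ weights. Defaults
$\lambda_{coord} = \lambda_{obj} = 5$, $\lambda_{noobj} = 0.5$: the
magnitudes follow the ancestor detector's convention, and the constraint
that matters scientifically is $\lambda_{noobj} \ll \lambda_{obj}$ —
an unlabeled true particle sits in a "no-object" cell, so sparse manual
picking must be penalized lightly; this is what lets training converge
when only a fraction of the particles in a micrograph are labeled. Batch
reduction is sum over cells, mean over images, keeping magnitudes
comparable across batch sizes.

## Training

Training data are labeled micrographs; every micrograph is augmented
before each epoch with a random subset of six operators (each enabled
method fires independently with probability 0.3): Gaussian blur (SD 0–3
px), average blur (mask 2–7 px), horizontal/vertical flips (boxes
transformed identically), additive Gaussian noise (SD a fraction 0.01–0.10
of the image SD), pixel dropout (1–10 % of pixels replaced by the image
mean) and contrast normalization (scale 0.5–2 around the median; the
median pixel is a fixed point). The noise and contrast ranges and the 0.3
application law are this package's defaults — the operator list fixes the
family, not the law. Blurs use reflective padding so constants are
preserved and no edge darkening is introduced.

Optimization is ADAM on the loss above (default learning rate 1e-3, batch
4, at most 100 epochs). The split is always micrograph-level, 20 % by
default; validation loss is computed without augmentation or dropout, and
training returns the weights of the best validation epoch, stopping after
`early_stop_patience + 1` epochs without improvement. A learning rate of
1e-4 is stable but needs several times more epochs on the reduced
configuration; 1e-3 converges within ~30 epochs on every study set used
here without divergence, so it is the default (all of this is
configurable, and none of it is stated by the detector's originators).

Batch normalization uses per-batch statistics during training and running
averages (momentum 0.9) at prediction, so inference is deterministic.
Weights are He-initialized with the leaky-ReLU variance correction
$2/((1+\alpha^2)\,\text{fan-in})$; the detection head's confidence and
class biases start at −2 so the initial objectness prior is low — without
this, the no-object loss term dominates the first epochs. The numeric
epsilon in batch normalization is 1e-5; checkpoints round-trip bit-exactly
through R serialization.

## Picking

Large micrographs are processed as $n \times n$ overlapping patches
(default overlap fraction 0.2, last patch flush with the image edge), each
downscaled to the network input — by exact block averaging when the factor
is an integer, bilinear resampling otherwise, both with pixel-center
coordinate conventions so box coordinates map exactly. Decoded boxes are
mapped back to micrograph pixels; duplicates from overlapping patches are
removed by greedy confidence-descending non-maximum suppression (default
IOU 0.3). The originators do not describe their cross-patch
de-duplication; NMS is this package's choice because it is
order-independent and testable (idempotence is asserted). Detections in
overlap margins are kept and resolved purely by NMS. Output boxes are
clipped to the micrograph bounds, never dropped. Default operating
threshold 0.3; the precision-recall evaluation sweeps all thresholds
anyway.

## Evaluation

Picks are matched to ground truth greedily in descending confidence; a
pick is a true positive if its IOU with a still-unmatched truth box
exceeds 0.6 (strictly — the cutoff is read literally). Precision is 1 with
no picks, recall 1 with no truths, so the curve is anchored and the
integral well defined. The PR curve takes one operating point per distinct
confidence; because greedy assignments of higher-confidence picks never
depend on lower-confidence ones, the single-pass cumulative curve equals
re-matching from scratch at every threshold (a property the tests assert
against a brute-force oracle). The AUC integrates precision over recall by
the trapezoidal rule, anchored at recall 0 with the precision of the
highest-confidence point; whether the original evaluation used trapezoidal
or step integration is unstated, and the difference is far below the
tolerances used anywhere here. Mean IOU is reported over matched pairs
only and absent when there are none.

## The synthetic-micrograph generator

Each simulated micrograph plants randomly rotated copies of a synthetic
template at rejection-sampled positions (pairwise center distance at least
0.75 × template size by default), then applies, in order: zero-mean
Gaussian *structural* noise with SD $88k$; the contrast transfer function
$\mathrm{CTF}(s) = -\left[\sqrt{1-A^2}\sin\gamma(s) +
A\cos\gamma(s)\right] e^{-Bs^2/4}$ with
$\gamma(s) = \pi\lambda\Delta z s^2 - \frac{\pi}{2} C_s \lambda^3 s^4$ at
defocus $\Delta z$ = 2.5 µm, 300 kV ($\lambda \approx 0.0197$ Å),
amplitude contrast $A$ = 0.1 and $B$ = 200 Å²; and zero-mean Gaussian
*shot/digitization* noise with SD $51k$. Spherical aberration (2.0 mm) and
pixel size (1.2 Å) are not part of the published recipe but are required
to evaluate $\gamma$; both are configuration. The default set is 20
micrographs of 250 particles at five noise levels $k \in \{1,4,6,8,10\}$.

The template is a reproducible lumpy soft-edged blob (random Gaussian
bumps inside a sigmoid-edged circular support) standing in for projections
of a real ion-channel density map, which is deliberately out of scope. Its
peak amplitude (default 570) was set with the simulator's own SNR
estimator so that the full-scale $k=1$ set lands at micrograph-level SNR
≈ 1.25, the low-noise regime reported for simulated sets of this kind;
the measured SNR series then decreases monotonically in $k$ into the
"particles barely visible" regime near $k = 8$–10. Empirical SNR is
defined as the variance of the CTF-filtered clean composite divided by
the variance of everything added on top of it.

What the generator does *not* emulate: real projection structure over
orientations (the template only rotates in-plane), ice gradients, carbon
edges, crystalline-ice contamination, beam-induced motion, or correlated
detector noise. Tests passing on this generator therefore demonstrate
that the pipeline — encoding, loss, optimization, patching, decoding,
suppression, scoring — works end to end and is robust to the modeled
noise chain; they do not certify picking quality on real micrographs with
structured contaminants.

## Problem sizes used by the shipped tests and acceptance script

Training the full 1024-px configuration is a GPU-scale job; the shipped
tests and `scripts/acceptance.R` run the reduced configuration (input
256, filter schedule capped at 32) on study sets of 20 micrographs of
512 px with 10 particles of 128 px each, split 15 training / 4
validation. This scales the micrograph down while preserving the
quantity that governs the encoding: particles per grid cell. At full
scale the particle box (64 px default) spans two 32-px cells and the
hard-core spacing (0.75 × box) exceeds the cell diagonal, so no two
centers can share a cell; the 512/128/256 geometry reproduces exactly
that relation (cells are 64 micrograph pixels after the 2× downscale,
spacing 96 > 64√2). One box per cell then loses no ground truth, and
the recall ceiling of the encoding is 1.

At these sizes one training run is roughly three minutes on a single CPU
core; measured on the pinned seeds, the reduced detector reaches pooled
validation AUC ≈ 1.0 and mean IOU ≈ 0.86 at $k=1$, and keeps AUC well
above 0.8 at $k=6$ and 0.6 at $k=8$ — the qualitative noise-robustness
pattern of the full-scale detector, at desk scale. The sparse-label
property is exercised by deleting 80 % of the training boxes (validation
labels stay complete), mirroring how sparse manual picking behaves.

## Known limitations

- The from-scratch CNN runs on one CPU core; it is deliberately small.
  The full 1024-px schedule can be built and audited but not trained at
  desk scale.
- MRC support covers single-image little-endian modes 0/1/2 — the common
  case for motion-corrected micrographs — not stacks, movies, or 4-bit
  packed data.
- The EMAN1 y-axis convention varies between ecosystems; a `flip_y`
  reader/writer flag covers both, and round-trips are only guaranteed
  with a consistent flag.
- The reference box is physical (micrograph pixels), so decoded box sizes
  are independent of the patch layout; the convolutional features are not
  scale invariant, however, so a detector trained at one patch scale
  should be applied with the same layout (training can pool several
  layouts via `patches_n = c(1, 2)` when layout robustness is needed).
- Greedy (not optimal-assignment) matching is used for evaluation, as is
  standard in detection; with heavily overlapping picks the two can
  differ slightly.
- `fit_detector` holds all training micrographs in memory; hundreds of
  4k-micrographs would need a streaming loader, which the study-set sizes
  here do not require.
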