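# cryopick

Single-shot convolutional particle picking for cryo-EM micrographs.

In single-particle cryo-electron microscopy, tens of thousands of
individual macromolecule projections must be located in noisy micrographs
before any averaging or 3-D reconstruction can happen. Template matching
mis-fires on contaminated or low-contrast data, and sliding-window CNN
classifiers are slow and need labeled negatives. cryopick implements the
alternative that modern object detection uses: a convolutional network
looks at the whole (possibly patched) micrograph once, divides it into an
S × S grid, and for every grid cell regresses whether a particle box
center lies in that cell, where exactly it sits, and how large the box is.
Training needs only positively labeled particles — background and
contamination are implicitly negative — and tolerates sparsely picked
micrographs.

The package is aimed at method developers and practitioners who want a
fully inspectable, dependency-light implementation of this detector
family in R: the network (21 feature convolutions + passthrough + 1 × 1
detection head), its four-term loss, the training-time augmentation
suite, patch-based inference with non-maximum suppression, coordinate
I/O in the standard cryo-EM formats (MRC2014, EMAN1 `.box`, RELION
`.star`), precision-recall/IOU evaluation, and a parameterized
synthetic-micrograph generator (planted particles → structural noise →
CTF → shot noise) so the entire pipeline trains and validates with known
ground truth on one CPU.

## The model

Per grid cell *i* the network predicts offsets $(\hat x_i, \hat y_i)$ of
the box center within the cell, box sides $(\hat w_i, \hat h_i)$ relative
to a single anchor, and a confidence $\hat C_i$. Training minimizes

```
L =  λ_coord Σᵢ 1ᵢ[(xᵢ−x̂ᵢ)² + (yᵢ−ŷᵢ)²]
   + λ_coord Σᵢ 1ᵢ[(√wᵢ−√ŵᵢ)² + (√hᵢ−√ĥᵢ)²]
   + λ_obj   Σᵢ 1ᵢ (Cᵢ−Ĉᵢ)²
   + λ_noobj Σᵢ (1−1ᵢ)(Cᵢ−Ĉᵢ)²
```

with `1ᵢ` indicating cells that contain a box center, and
`λ_noobj ≪ λ_obj` so that unlabeled true particles (false negatives in
the training labels) are penalized lightly — the property that makes
sparse manual picking workable. Optimization is ADAM with early stopping
on a held-out micrograph-level validation split. Picks are scored against
ground truth by greedy IOU matching (true positive above IOU 0.6),
precision-recall curves, their integral (AUC), and the mean IOU of
matched pairs.

## Worked example

Simulate a labeled study set, train the reduced (CPU-scale) detector,
and score the held-out micrographs:

```r
library(cryopick)

spec <- sim_spec(k = 1, n_micrographs = 20, micrograph_size = 512,
                 template_size = 128, particles_per_micrograph = 10,
                 seed = 11)
sims <- simulate_dataset(spec)
round(empirical_snr(sims[[1]]), 2)
#> [1] 0.16

samples <- lapply(sims[1:19], function(s)
  list(micrograph = s$micrograph, boxes = s$boxes))
model <- build_detector(network_config(input_size = 256, reduced = TRUE),
                        seed = 7)
model <- fit_detector(model, samples,
                      train_config(seed = 11, box_size = 128,
                                   max_epochs = 40))

val <- split_dataset(19, 0.21, seed = 11)$validation
picks <- lapply(val, function(i)
  pick_particles(model, sims[[i]]$micrograph, conf_threshold = 0.3))
truth <- lapply(val, function(i) sims[[i]]$boxes)
pooled_pr_curve(picks, truth, iou_threshold = 0.6)$auc
#> [1] 1

mr <- match_picks(picks[[1]], truth[[1]], iou_threshold = 0.6)
c(tp = mr$tp, fp = mr$fp, fn = mr$fn, mean_iou = round(mean_iou(mr), 2))
#>       tp       fp       fn mean_iou
#>    10.00     0.00     0.00     0.87
```

The AUC of 1 means every planted particle on the four held-out
micrographs is recovered before the first false positive; the mean IOU
of ~0.87 says the predicted boxes overlap the truth boxes to ~87 % of
their union, i.e. centering errors of only a few pixels at a 128-px box.
Training this configuration takes around three minutes on one CPU core.

The same pipeline is scriptable from a shell via `inst/cli/cryopick`
(subcommands `simulate`, `train`, `predict`, `evaluate`).

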