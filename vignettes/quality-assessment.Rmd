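---
title: "Two-layer quality assessment of whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer quality assessment of whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideqc)
```

## The problem

Digitised histopathology slides (whole-slide images, WSIs) carry quality
defects that matter both for diagnostic review and for any image-analysis
model trained on them: out-of-focus regions, faded or low-contrast H&E
staining, folded tissue, and obscuring material such as ink, dirt, air
bubbles, coverslip edges and diathermy damage. Manual quality review of
thousands of slides is unfeasible, and single-purpose detectors (focus
only, brightness only) miss most of this taxonomy.

`slideqc` implements a two-layer assessment. The first layer scores every
256 x 256 tissue patch at 5x magnification with a multi-label
convolutional regressor; the second layer maps summary statistics of the
resulting per-category *quality overlays* to slide-level scores: a binary
usability call, and focus and staining scores on a 0-10 scale where a
score of 4 or less is a fail, 5-6 a pass, 7-8 good and 9-10 excellent.
Failing slides receive an intervention recommendation (re-scan, re-stain,
or manual review).

## The patch-level model

Each patch gets a six-component target
`y = (y1, ..., y6)`:

| component | meaning | domain |
|---|---|---|
| `y1` | usable for diagnosis | 0/1 |
| `y2` | no artefact at all | 0/1 |
| `y3` | staining / H&E-contrast issue severity | 0, 0.5, 1 |
| `y4` | focus issue severity | 0, 0.5, 1 |
| `y5` | tissue folding present | 0/1 |
| `y6` | other artefact present (ink, dirt, bubble, coverslip edge, diathermy, ...) | 0/1 |

The domains cross to `3^2 * 2^4 = 144` unique label combinations
(`count_label_combinations()`). Rather than six separate classifiers, one
network with six *linear* outputs is fitted as a multivariate regression,
which shares features across correlated labels and -- because subjective
quality annotation is inherently noisy -- is trained with the Huber loss

$$L_\delta(x, y) = \begin{cases} \tfrac12 (x-y)^2 & |x-y| \le \delta \\
\delta\,|x-y| - \tfrac12 \delta^2 & \text{otherwise}, \end{cases}$$

with `delta = 1`: quadratic near the target like mean-squared error,
linear in the tails so label outliers do not dominate. `huber_loss()`
exposes the reduction used (mean over outputs and batch).

The architecture is a residual CNN family: a 3x3 stride-2 stem, stages of
basic blocks (3x3 conv + batch norm, identity or 1x1-projection
shortcuts), global average pooling, a batch-normalised embedding and a
linear 6-output head. The default configuration
(`qnet_config()`: widths 64/128/256/512, two blocks per stage, 224 px
input) is the 18-layer family; `qnet_config_reduced()` (widths 16/32/64,
one block per stage, 64 px input) is a CPU-scale backbone with the same
contract. Defaults follow the training recipe: batch size 100, Adam with
learning rate 1e-4, 200 epochs, model selection at the epoch of minimum
validation loss, an 80/10/10 train/test/validation split stratified on
unique label combinations, and an inverse-combination-frequency weighted
batch sampler against label imbalance.

Two initialisation choices matter for short training budgets and are the
package's own: the pooled embedding is batch-normalised before the head,
and the head itself starts at zero. Predictions then start at the origin
and every subsequent movement of an output is learned, sign-correct
signal on standardised features -- with only tens of optimiser steps, a
randomly initialised head would otherwise dominate the ranking the
outputs produce. Outputs remain unbounded (linear activations); clamping
to [0, 1] happens only where overlays are assembled.

### Augmentation

Quality is exactly what standard photometric augmentation destroys: blur,
contrast, brightness, saturation or noise transforms would change the
label. The policy here (`draw_augment_params()`) therefore permits only
rotations by 0/90/180/270 degrees, horizontal/vertical flips, affine
shear in ±10 degrees, translation up to ±5% per axis, and hue rotation in
±30 degrees (interpreted on the 0-360 hue circle). The image warp and the
artefact-geometry transform share one affine code path, so tests can
recompute the ground-truth label from the transformed geometry and verify
it never changes. Because the optimiser loop runs in compiled code with
persistent state, training-time augmentation is realised by expanding the
training partition with augmented copies (`augment_copies` per patch)
rather than by per-epoch redraws; the admissible transform set is
identical.

## The synthetic-slide generator

No external cohort ships with the package. Instead, `generate_base_patch()`
builds H&E-like patches in stain-density space: smooth eosin stroma with
background gaps, elliptical hematoxylin nuclei, density speckle, and a
Beer-Lambert conversion through a canonical H&E absorbance matrix (so
stain deconvolution round-trips by construction). `apply_artefact()`
injects the artefact taxonomy with ground truth:

- **focus_blur** -- Gaussian blur, severity-indexed sigma of 2 (slight)
  or 6 (severe) at the 256 px working scale. The two bands are separable
  both by eye and by gradient-based focus measures.
- **stain_fade** -- attenuation in optical-density space: hematoxylin
  density scaled by `1 - 0.85 s` and eosin by `1 - 0.4 s` at severity
  `s`, reproducing loss of nuclear detail and global contrast. Fade is
  deliberately *not* a brightness change: staining issues do not reduce
  to image brightness.
- **fold** -- a translated copy of nearby tissue composited by
  optical-density *addition* inside the fold region: locally doubled
  stain structure. A fold is therefore not reproducible by darkening
  alone (tests assert a large residual after the best global density
  gain fit), which is exactly the failure mode of intensity-based
  hand-crafted features.
- **ink / dirt / bubble / coverslip_edge / diathermy** -- opaque blobs,
  speckle clusters, rings, straight bands and desaturated scorch
  texture.

`label_for()` turns the injected specs into the six-component label: the
severities take maxima, folding and other-kind artefacts set their flags,
`y2` requires all components clean, and usability is 0 exactly when focus
or staining is severe or when obscuring material covers at least half the
patch. In pathologist annotation practice, patch usability is a
judgement call; this deterministic rule is the package's oracle so that
every downstream stage has exact ground truth. Obscuring regions are drawn
either clearly sub-critical (5-35% coverage) or clearly super-critical
(55-90%) so that the 50% rule stays unambiguous under ±5% translation
augmentation.

`generate_dataset()` draws a labelled patch set from a configurable
artefact mix. The default mix (43% clean, 8/12% slight/severe blur, 6/8%
slight/severe fade, 12% folds, 21% obscuring kinds, plus a 15% chance of
a second artefact of a different kind) gives every task both classes at
realistic imbalance. `compose_slide()` tiles base patches with per-cell
artefact lists into a composite slide and returns the implied
ground-truth overlays; `reference_slide_scores()` converts these into
slide-level reference scores (focus/stain = `10 * (1 - mean severity)`;
a slide counts as usable when at most 30% of its tissue cells are
unusable), emulating aggregated assessor scores for synthetic cohorts.

What the generator does *not* model: realistic tissue morphology beyond
nuclei-on-stroma texture, scanner-specific focus maps, frozen-section
appearance, or annotation noise. Passing tests on synthetic data
demonstrate that the pipeline's mechanics -- labels, losses, splits,
overlays, scoring -- are correct and that the network can learn the
injected artefact physics; they do not certify performance on any real
cohort.

## Slide layer

`segment_tissue()` replaces an external tissue-segmentation model with
Otsu thresholding on the HSV saturation channel plus small-object removal
and hole filling (stained tissue is saturated; glass is not). Tiling
(`tile_grid()`) keeps full 256 px tiles whose tissue fraction reaches
`min_tissue_fraction` (default 0.1; no published cut-off exists, so it is
configuration), with 0-based half-open pixel windows in row-major order.
For pyramidal sources the level nearest the working magnification is read
and bilinearly resampled to the exact scale.

`assemble_overlays()` clamps the six predictions per kept tile to [0, 1]
and arranges them on the tile grid; cells without tissue stay absent.
`overlay_stats()` reports the mean and *population* variance over present
cells (the choice of variance convention is recorded here; it is not
specified upstream). `fit_slide_models()` fits three ordinary
least-squares regressions -- usability on [0, 1], focus and staining on
[0, 10] -- from the 12 overlay statistics (mean and variance of all six
overlays; which overlays feed which model is unstated in the source
method, so the full set is the default and configurable), on a 60/40
slide split stratified on usability crossed with quartile-binned focus
scores. Predictions are clipped to their ranges; usability is binarised
at 0.5 (configurable, as any local preference may shift it).

Interventions follow `recommend_intervention()`: a focus fail suggests
re-scanning *unless* the mean "other"-artefact overlay exceeds 0.3 --
re-scanning cannot remove ink or dirt, so those slides go to manual
review; a staining fail suggests re-staining; an unusable slide with no
failing score also goes to manual review. The 0.3 burden cut is a
documented heuristic of this package.

For multi-assessor reference scores, `aggregate_assessors()` uses the
conservative AND rule for usability (a slide is usable only if every
assessor says so) and averages the focus and staining scores.

## Baselines and diagnostics

`features_ours()` and `features_histoqc()` implement the two hand-crafted
feature banks used for comparison: gradient/Laplacian focus measures
(Tenengrad, variance of Laplacian, modified Laplacian LAP2),
contrast measures (RMS, Michelson), Gaussian-difference, per-channel
statistics of RGB/HSV/stain-density channels, Otsu threshold, and (in the
HistoQC-style bank) Gaussian/Laplace/Frangi/Gabor filter means and a
10-bin uniform LBP histogram. Kernel choices are fixed and recorded: 3x3
Sobel and Laplacian, Gaussian sigma 3, Gabor at 4 orientations x 2
frequencies, Frangi at sigma 2; the Gaussian-difference feature uses the
grayscale image. `train_rf_per_task()` fits one random forest per task
(500 trees, class-balanced weights) and `compare_banks()` reports
held-out ROC-AUC per task for both banks and the network on one split.
The expected qualitative picture on synthetic folds mirrors practice:
intensity-statistics banks confuse folds with generally darker patches,
while the CNN separates doubled structure from a global gain.

`embed_and_compare()` quantifies cohort similarity: penultimate-layer
embeddings, a 2-component PCA fitted on the union, per-cohort 2D kernel
density estimates on a shared grid (normal-reference bandwidth from the
union, recorded in the output), and overlap as the integrated minimum of
the normalised densities -- 1 for identical feature distributions, 0 for
disjoint ones. The overlap statistic is this package's quantification of
"good feature-space overlap"; no reference value exists for it.

## Numerical and design choices

- 0-based, half-open pixel coordinates, row-major tile ordering
  everywhere; coordinate round-trips are exact by construction.
- Stain deconvolution uses a fixed canonical absorbance matrix
  (hematoxylin/eosin/residual rows, unit-normalised); densities are
  clipped at zero. Optical density uses `-log10(I)` with intensities
  floored at 1e-6.
- Every stochastic component (generator, splits, samplers, forests,
  training) is a pure function of its seed; the RNG state of the caller
  is always restored.
- The split allocates per label combination by largest remainder;
  combinations with fewer members than partitions go entirely to
  training (the source method does not say how singletons were split).
- Targets are regressed as-is; the three-level severities are never
  thresholded during training.
- Training aborts with a diagnostic on non-finite loss; batch norm
  requires at least two samples per batch, so trailing one-sample
  batches are dropped.
- Rectangular and disc artefact regions become polygons under the
  augmentation affine; coverage is computed by Sutherland-Hodgman
  clipping and the shoelace formula.

## Problem sizes used by the test-suite experiments

The packaged experiments run at CPU scale, chosen as the smallest sizes
at which the studied effects are comfortably detectable: the learning
property trains the reduced backbone on one 2,000-patch dataset at the
default mix (five training seeds vary split, initialisation and
sampling); the fold-versus-darkness comparison builds one balanced
240-patch task (120 folds, 120 darkened) and refits all three methods
on five seeded 75/15/10 splits; the end-to-end experiment composes 100
synthetic slides of 4 x 4 tiles, profiles them with a reduced network
trained once to convergence on 1,500 patches, and fits the slide models
on a 60/40 split. Per-slide artefact burden in that cohort follows the
shape of real slide libraries -- mostly clean slides (65% with under
20% affected tiles), a clearly degraded minority (15% with 50-85%
affected), and some borderline cases -- so that the usability reference
is identifiable from 16-tile overlays: a cohort concentrated at the
0.3 unusable-fraction boundary would cap achievable agreement well
below 1 even for error-free patch predictions, as the overlay fraction
is quantised in steps of 1/16. The full-size configuration (224 px
input, 18-layer backbone, 200 epochs) uses the same code path.

## Limitations

- The synthetic generator's artefact physics are idealised; severity
  calibration ("slight" sigma 2 vs "severe" sigma 6, fade factors) is
  the package's own, since no quantitative definition of slight/severe
  exists.
- No pre-trained weights ship with the package; `qnet()` trains from
  scratch (ImageNet-style initialisation is not available offline).
- The usability regression is a linear probability model, taken
  literally from the stated method; it is not calibrated.
- `read_slide()` handles pyramidal/plain TIFF and PNG; vendor-specific
  WSI containers and their metadata are out of scope.
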