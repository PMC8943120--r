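# slideqc

Automated quality control of whole-slide H&E histopathology images
(WSIs), for slide-library curators and computational-pathology groups
who need to triage thousands of scanned slides: which images are usable
for diagnosis or model training, which artefacts they carry, and which
would actually improve from re-scanning or re-staining.

## What it computes

The package implements a two-layer assessment:

1. **Patch layer.** Every 256 × 256 tissue patch at 5× magnification is
   scored by a multi-label residual CNN with six linear outputs aligned
   with the annotation schema
   `y = (y1 usability, y2 no-artefact, y3 staining, y4 focus, y5 folding,
   y6 other)`, where `y3, y4 ∈ {0, 0.5, 1}` (none/slight/severe) and the
   rest are binary — a target space of `3² × 2⁴ = 144` unique label
   combinations. The network is trained as a multivariate regression
   with the noise-robust Huber loss

   L_δ(x, y) = ½(x−y)² for |x−y| ≤ δ, δ|x−y| − ½δ² otherwise (δ = 1),

   with Adam (batch 100, learning rate 1e-4, 200 epochs by default), an
   80/10/10 split stratified on unique label combinations, an
   inverse-frequency weighted batch sampler, and a label-preserving
   augmentation policy (90° rotations, flips, ±10° shear, ±5%
   translation, ±30° hue — never blur/contrast/noise, which would change
   the quality label itself).

2. **Slide layer.** Patch predictions are clamped to [0, 1] and
   assembled into six per-category quality overlays on the tile grid;
   the mean and variance of each overlay feed three linear regressions
   predicting slide-level usability (0/1 at a 0.5 cut), and focus and
   staining scores on the 0–10 scale where ≤ 4 is a fail. Failing
   slides get an intervention recommendation: re-scan for focus
   failures (suppressed when obscuring "other" artefacts dominate,
   since re-scanning cannot remove ink or dirt), re-stain for staining
   failures, manual review otherwise.

Everything is testable without external data: a synthetic-slide module
generates H&E-like patches in stain-density space and injects
ground-truth-labelled artefacts (blur, stain fade, optical-density
folds, ink, dirt, bubbles, coverslip edges, diathermy). Hand-crafted
feature banks (Tenengrad, Laplacian measures, contrast, colour and
stain-density statistics, LBP, Frangi/Gabor) with per-task random
forests are included as comparison baselines, plus cohort summaries and
a PCA/KDE feature-space overlap diagnostic.

## Worked example

Train a compact model on synthetic labelled patches, then profile a
composed slide containing one severely blurred tile and one inked tile:

```r
library(slideqc)

ds  <- generate_dataset(1500, seed = 42, out_size = 64)
fit <- qnet(ds, config = qnet_config_reduced(epochs = 12,
                                             learning_rate = 1e-3), seed = 1)

grid <- matrix(list(), 3, 3)
for (i in seq_along(grid)) grid[[i]] <- list()
grid[[1, 3]] <- list(artefact_spec("focus_blur", severity = 1))
grid[[3, 1]] <- list(artefact_spec("ink",
  region = list(shape = "rect", x0 = 0, y0 = 0, x1 = 220, y1 = 220), seed = 2))
slide <- compose_slide(grid, seed = 7, size = 256)

prof <- profile_slide(slide, fit, use_mask = FALSE)
round(prof$overlays$usability, 2)
#>      [,1] [,2] [,3]
#> [1,] 1.00 0.77 0.19
#> [2,] 1.00 0.93 1.00
#> [3,] 0.18 1.00 1.00
round(prof$overlays$focus, 2)
#>      [,1] [,2] [,3]
#> [1,] 0.00    0 0.78
#> [2,] 0.00    0 0.00
#> [3,] 0.49    0 0.00
round(prof$overlays$other, 2)
#>      [,1] [,2] [,3]
#> [1,]    0 0.00 0.00
#> [2,]    0 0.00 0.06
#> [3,]    1 0.03 0.06
```

The blurred tile (row 1, col 3) is flagged unusable (0.19) through the
focus overlay (0.78); the inked tile (row 3, col 1) is flagged unusable
(0.18) primarily through the "other" overlay (1.0) -- the distinction
that decides between a re-scan recommendation and manual review (the
partial focus co-activation on the inked tile is the classic
obscured-looks-blurry confusion; `compare_banks()` quantifies how the
learned model compares with intensity-based features on such
ambiguities). `prof$stats` holds
the 12 overlay statistics (`mean_usability = 0.785`,
`mean_focus = 0.141`, `mean_other = 0.127`, ...) that slide-level
models consume via `fit_slide_models()` / `predict()`.
`render_heatmap()` writes the colour-coded overlay PNGs, and
`inst/cli/slideqc` exposes the same pipeline as shell subcommands
(`synth`, `train-patch`, `run`, `fit-slide`, `compare-banks`,
`report`).

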