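# dafdnet

Detection of thin, low-contrast fracture lines in grayscale,
radiograph-like images. Nondisplaced femoral-neck fractures (Garden
types I–II) appear on anterior–posterior pelvis radiographs as faint,
1–3 px dark lines crossing the femoral neck, and are easy to miss both
for readers and for generic segmentation networks, whose repeated
convolutions wash out such tiny intensity dips. This package implements
a *direction-aware* encoder–decoder segmentation network for that
problem, the two-stage localization→detection pipeline around it, the
region-overlap evaluation suite, and a synthetic phantom generator that
makes the whole system testable without clinical data. It is aimed at
researchers in medical image analysis who want a fully inspectable,
dependency-light reference implementation in R.

## The model

The network couples two encoder paths over three resolution stages:

* **Direction-aware path.** A fixed (non-learned) bank of 2-D Gabor
  wavelets acts as the first feature extractor:

  ```
  G_{u,v}(z) = (||k||^2/σ²) · exp(−||k||²||z||²/(2σ²)) · [exp(i k·z) − exp(−σ²/2)]
  ```

  with wave vector magnitude `k_v = (π/2)/2^(v−1)` (octave scales
  `v = 1..4`), direction `φ_u = uπ/U` for `U = 8` orientations, and
  envelope width `σ = 2π`. The 8 × 4 = 32 magnitude responses `Gab_i`
  give orientation- and frequency-indexed edge evidence that survives
  depth because it is computed once, directly from the image.

* **Ghost path.** SE-ghost modules `GhoM_i`: a cheap primary
  convolution produces half the channels; a squeeze-and-excitation
  block gates those channels and the reweighted copy is concatenated
  back, giving full width at roughly half the parameters of a plain
  convolution.

Per stage the two paths are concatenated (`GG_i`), refined by a
size-preserving 2×2 mean, 3×3 convolution and feature normalization
(`PF_i`), re-joined with the ghost features, and passed through
channel-then-spatial attention (`A_i`). The decoder upsamples and
concatenates `A_3 → A_2 → A_1` and ends in a 1×1 convolution and
sigmoid: a per-pixel fracture probability map at input resolution,
trained by mean-squared error against binary masks with Adam
(learning rate warmed up 1e-5 → 4e-5 in 1e-5 steps, batches of 12).

Detection runs in two phases: an ROI network segments the femoral
neck on the full image, the padded bounding box of its largest
component is cropped and resampled, and a second network marks the
fracture line inside the crop; boxes map back to full-image
coordinates exactly. Evaluation reports bounding-box IOU plus
pixel-mask Dice and Jaccard (`J = D/(2−D)`), binned at IOU 0.2/0.5.

Forward *and* backward passes are implemented in the package itself
(im2col + BLAS GEMM convolutions via RcppArmadillo); there is no deep
learning framework underneath, so every gradient is testable against
finite differences — and is.

## Worked example

```r
library(dafdnet)

# a 128 px synthetic femoral-neck phantom with a faint crack
rec <- generate_phantom(phantom_spec(image_size = 128,
                                     crack_contrast = 0.09, seed = 101))
mean(rec$fracture_mask)                 # foreground fraction of the crack
#> [1] 0.01263428

# a reduced network, trained to overfit four phantoms
cfg <- dafdnet_config(input_size = 128, stage_channels = c(8, 16, 32),
                      pf_channels = c(8, 16, 32), gabor_scales = 1:2)
recs  <- lapply(101:104, function(s)
  generate_phantom(phantom_spec(image_size = 128, crack_contrast = 0.09,
                                seed = s)))
fit <- dafdnet_train(build_dafdnet(cfg, seed = 1),
                     lapply(recs, `[[`, "image"),
                     lapply(recs, function(r) r$fracture_mask * 1),
                     train_config(batch_size = 4, lr_init = 1e-3,
                                  lr_max = 1e-3, lr_step = 0,
                                  epochs = 40, seed = 1))
tail(fit$history$loss, 1)               # well under the 0.012 background loss
#> [1] 0.001116169

pred <- dafdnet_forward(fit$model, recs[[1]]$image)$prob
dice(pred >= 0.5, recs[[1]]$fracture_mask)
#> [1] 0.955665
```

The final training loss (0.0011) is an order of magnitude below the
all-background predictor's loss (the mean crack foreground fraction,
≈0.012), and the thresholded probability map overlaps the true crack
mask with Dice 0.96 — the network has genuinely localized the
fracture line, not just predicted "background everywhere".

A shell interface wraps the same functions
(`inst/cli/dafdnet.R generate|train|predict|evaluate`); see
`?dafd_main`.

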