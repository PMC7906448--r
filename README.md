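# pigmorph

Image-based weighing of growing pigs from a ceiling-mounted RGB-D camera.
`pigmorph` turns top-view video of a freely moving pig into morphological
image descriptors — body length and width (pixels, from the RGB frames),
height (meters, from the depth frames) and a derived volume — and forecasts
live body weight 1–4 days ahead with random-intercept linear mixed models
under sliding-window time-series cross-validation.

It is written for precision-livestock researchers who have (or want to
prototype against) paired 8-bit RGB frames and metric depth maps of a
single animal in a pen, plus daily scale weights. Because such video is
rarely shareable, the package includes a synthetic top-view scene generator
with known ground truth; every processing stage is validated against it.

## The measurement chain

Per RGB frame: grayscale → Otsu threshold → largest 8-connected component
→ morphological opening (Euclidean disc, 15 px) to remove the tail →
minimum-area rotated bounding box of the contour (exact rotating calipers).
QC drops frames with no object, a box corner within 2 px of the frame edge,
or a segmented area outside 1–40% of the frame. Per depth frame: the same
segmentation on a single-channel depth rendering, then height = camera
height (2.25 m) − median depth in a 5×5 window at the mask centroid.
Per-frame heights are split standing/sitting by 1-D 2-means; the video's
estimates are medians (length, width over QC-passing frames; height over
the standing cluster).

## The forecasting model

For animal *i* on day *t*:

    y_it = β0 + βL·L_it + βW·W_it + βH·H_it + a_i + e_it,
    a_i ~ N(0, σ²_a),   e_it ~ N(0, σ²_e)

fitted by REML (`lme4`); volume is excluded from the fixed effects to avoid
multicollinearity. Forecasts use the descriptors alone (**LMM1**) or
descriptors plus each animal's BLUP intercept (**LMM2**). A 14-day window
slides one day at a time; horizons 1–4 days are scored per slide across
animals by prediction R² (squared Pearson correlation by default) and MAE.

## Worked example

```r
library(pigmorph)

# a 300-frame synthetic video: true body 200 x 84 px, 0.50 m tall,
# 20% border-touching frames, 10% motion-blurred, 5 mm depth noise
cfg <- scene_config(pig_length = 200, pig_width = 84, pig_height = 0.5,
                    standing_fraction = 0.7, border_fraction = 0.2,
                    blur_fraction = 0.1, depth_noise_sd = 5)
video <- simulate_video(cfg, n_frames = 300, seed = 42)

m <- measure_video(video)
table(m$qc)
#> BORDER_ATTACHED              OK
#>              68             232
aggregate_length_width(m)[c("median_length_px", "median_width_px")]
#> $median_length_px [1] 200.9045
#> $median_width_px  [1] 84.8

video_height(video, seed = 42)$height_m
#> [1] 0.499
```

The medians recover the true 200 × 84 px body within a pixel despite a
third of the frames being unusable, and the standing height lands within a
millimeter of the true 0.50 m. Forecasting on a simulated 8-animal,
38-day growth trial:

```r
sim <- simulate_growth(growth_config(rng_seed = 1))
cv  <- run_cv(sim$table)
summary(cv)
#>   model horizon n_slides   r2_min r2_median r2_max mae_median_kg
#> 1  LMM1       1       24 2.79e-07    0.0425  0.271         3.962
#> ...
#> 5  LMM2       1       24 8.92e-01    0.9669  0.994         0.862
#> 8  LMM2       4       21 8.89e-01    0.9653  0.988         0.847
```

With a 6 kg between-animal standard deviation, the animal effect carries
most of the cross-sectional signal: LMM2 (descriptors + BLUP) forecasts
with median R² ≈ 0.97 and sub-kilogram MAE, while LMM1 (descriptors alone)
is far weaker and less stable — the qualitative pattern this design is
meant to exhibit. Slide counts per horizon are 24/23/22/21.

A full pipeline (`run_pipeline()`, or the `inst/exec/pigmorph` script with
subcommands `simulate`, `measure`, `height`, `assemble`, `forecast`,
`run`) writes per-video measurements, the joined descriptor–weight table,
the 5×5 Pearson correlation matrix, per-slide forecast results, and a JSON
manifest with seeds, configuration and output checksums.

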