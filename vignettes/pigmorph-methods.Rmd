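---
title: "Measuring and forecasting pig body weight from top-view RGB-D video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and forecasting pig body weight from top-view RGB-D video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Weighing growing pigs on a scale is laborious and stressful for the animal.
A ceiling-mounted RGB-D camera over the pen offers a contact-free
alternative: top-view color frames give the animal's planar outline, and the
aligned depth map gives its height above the floor. From each daily video,
`pigmorph` extracts four morphological image descriptors — body length and
width in pixels, height in meters, and their product as a volume proxy — and
uses them to forecast live body weight one to four days ahead.

The pipeline is designed for *nonrestrained* animals: the pig walks, sits,
touches the pen fence and blurs frames by moving. Robustness therefore comes
from per-frame quality control plus median aggregation over the ~1,080
frames a 3-minute recording at 6 frames/s provides, rather than from any
single good frame.

## From frames to descriptors

**Length and width (RGB route).** Each frame is converted to 8-bit
grayscale (luminance weights 0.299/0.587/0.114), binarized with a global
Otsu threshold, and reduced to its largest 8-connected component. A
morphological opening with a Euclidean disc (diameter 15 px by default)
removes the tail, whose width is well below the kernel size, and the largest
component is re-extracted. The minimum-area rotated rectangle of the
component's boundary then proxies the body: its longer side is the spine
length, its shorter side the width. Quality control discards frames in this
order: no object found; any box corner within 2 px of the frame edge
(border attachment — part of the animal may be outside the view); component
area outside 1–40% of the frame (shape distortion or motion blur). The
per-video estimate is the median of each measure over the retained frames.

**Height (depth route).** The depth frame is reduced to a single channel —
the HSV hue channel for colorized depth renderings, or a min–max normalized
8-bit image for raw metric maps — and segmented by the same procedure. The
median depth in a 5×5 window around the mask centroid (ignoring invalid
zero pixels) gives the camera-to-animal distance, and subtracting it from
the camera-to-floor distance (2.25 m by default) gives the height. Because
the animal alternates between standing and sitting, the per-frame heights
are split by one-dimensional 2-means into two clusters; the cluster with the
higher median is taken as standing, and its median is the video's height.
If the cluster means differ by less than 0.05 m the video is treated as
single-posture and the clusters are merged.

**Volume.** `volume = length_px × width_px × height_m`, deliberately kept
in mixed units (px²·m): no pixel-to-metric calibration is attempted, since
the descriptors only need to be consistent proxies, not physical volumes.

## The forecasting model

For animal $i$ on day $t$, body weight is modelled with a random-intercept
linear mixed model, fitted by REML through `lme4`:

$$y_{it} = \beta_0 + \beta_L L_{it} + \beta_W W_{it} + \beta_H H_{it}
  + a_i + e_{it}, \qquad a_i \sim N(0, \sigma^2_a),\;
  e_{it} \sim N(0, \sigma^2_e).$$

Volume is never a fixed effect — it is the product of the other three and
would make the design multicollinear. Two prediction modes are compared:
**LMM1** uses the fixed effects only ($\hat y = x'\hat\beta$), and **LMM2**
adds each animal's predicted intercept (its BLUP from the training window),
exploiting the fact that the same animals are tracked through time.

Evaluation follows a move-forward time-series scheme: a 14-day window is
fitted and the weight $h \in \{1,2,3,4\}$ days after the window's last day
is forecast for every animal, the window sliding one day at a time. With 38
observation days this yields 24/23/22/21 slides for the four horizons. Each
slide is scored across animals by prediction $R^2$ and MAE.

**Which $R^2$?** The default is the squared Pearson correlation between
observed and forecast weights, which lies in $[0,1]$; the alternative
$1 - \mathrm{SSE}/\mathrm{SST}$ can be negative for poor out-of-sample fits
and is available via `r2_method = "ssr"`. We default to the squared
correlation because reported prediction $R^2$ ranges for this kind of
forecasting are strictly positive, which is inconsistent with the
$1-\mathrm{SSE}/\mathrm{SST}$ definition under weak models.

## The synthetic scene generator

The study's videos are not distributable, so the package ships a generator
that every stage is tested against:

* the animal is a filled rotated ellipse with a thin tail rectangle at one
  pole (so tail removal is actually exercised); intensities are uniform
  (animal 180, floor 70 by default);
* the depth surface equals the floor depth (2,250 mm for a 2.25 m camera)
  outside the animal, and inside it drops by
  $1000\,h\,(1 - 0.3\,r^2)$ mm, where $r$ is the normalized elliptical
  radius: full height at the spine, 70% at the outline. The quadratic taper
  keeps the surface flat near the centroid so centroid sampling recovers
  the nominal height exactly on noiseless frames;
* sitting frames scale the height by 0.55, giving the clearly bimodal
  height distribution the posture clustering needs;
* frames are independently standing/sitting, border-touching, or
  motion-blurred with configurable probabilities; border frames place the
  body centre close enough to a frame edge that the body must cross it;
  blur is a 15 px directional box filter;
* depth noise is Gaussian (5 mm by default), truncated at ±4 sd so depth
  maps stay within physical bounds;
* all randomness fans out from explicit seeds, one sub-seed per frame, and
  videos are rendered lazily (a materialized 1000-frame RGB-D video is
  ~6 GB, which nobody should hold in memory). Identical seeds reproduce
  identical frames bit for bit.

The longitudinal generator (`simulate_growth()`) mirrors a grower trial:
8 animals over 38 days, entering around 23 kg and gaining ~0.5 kg/d, with a
6 kg between-animal standard deviation, 1 kg residual, and weights generated
from the realized descriptors by the same random-intercept model the
forecaster fits. Descriptors grow linearly but fluctuate day to day
(defaults 2 px, 1 px, 0.01 m) — real daily measurements vary with posture
and gut fill, and without that fluctuation the three descriptors would be
collinear in time and the fixed effects unidentifiable. In the video-level
recovery studies, widths are sampled proportionally to lengths
(ratio ~0.40–0.46), matching the top-view aspect of a grower; independent
length/width sampling would produce implausible 5:1 bodies.

What the generator does *not* emulate: pig appearance statistics (texture,
coat color), multi-animal scenes, lens distortion, the vendor's depth
colorization, and non-elliptical postures (curled or twisted bodies).
Passing recovery tests on these scenes therefore demonstrates the
correctness of the measurement chain, not performance on camera data.

## Numerical choices

* **Thresholding.** Otsu's criterion on the 256-bin histogram; on plateaus
  (e.g. two-level synthetic images where any threshold separates equally
  well) the plateau midpoint is used. A fixed threshold can be configured.
* **Foreground polarity.** The side of the threshold whose largest
  connected component covers less than half the frame is taken as the
  animal, so the pipeline does not care whether the animal is lighter or
  darker than the floor.
* **Connectivity and ties.** 8-connectivity; equal-area components are
  broken by the smaller bounding-box top-left coordinate.
* **Opening.** Euclidean disc of radius $(d-1)/2$ implemented by exact
  squared distance transforms; pixels outside the image count as
  background, so objects clipped by the frame edge erode there (and dilate
  back), keeping border-touching animals detectable by the corner test.
* **Rotated box.** Exact rotating calipers over the convex hull (the
  optimal rectangle shares a side direction with a hull edge). Sides are
  reported under the pixel-footprint convention (point extent + 1 px), so
  an axis-aligned w×h pixel rectangle measures exactly w×h.
* **Centroid.** First moments over the opened mask, rounded half-up.
* **2-means.** `stats::kmeans` with 10 seeded restarts; with exactly two
  heights the two singleton clusters are formed directly; cluster-merge
  tolerance 0.05 m. In one dimension the optimum is a contiguous split of
  the sorted data, and `best_split_1d()` provides that exhaustive oracle.
* **REML, not ML**, for the mixed model, the conventional default for
  variance-component estimation; singular fits (e.g. $\hat\sigma^2_a = 0$)
  are tolerated, in which case LMM1 and LMM2 coincide.
* **Missing data.** The descriptor–weight join is an inner join; slides
  whose test day lacks some animals simply shrink; slides whose fit fails
  are skipped with a warning.

## Problem sizes used by the tests

The test-suite recovery studies use 50 videos × 1,000 frames for the
length/width study, 120-frame videos for height, 100 animals × 20 days ×
20 seeds for parameter recovery, and 20 master seeds of the 8×38 trial for
the cross-validation comparisons; `scripts/acceptance.R` re-runs scaled
versions (20 × 500-frame videos, 10 forecasting seeds) chosen to keep a
single-CPU run in the low minutes while leaving Monte-Carlo error well
below the tolerances tested.

## Storage formats

RGB frames are 8-bit PNG. Depth maps are stored as 16-bit grayscale TIFF
holding integer millimeters (invalid pixels as 0): a lossless, standard
container for scientific depth data with exact round-trip through
`tiff::readTIFF(as.is = TRUE)`. Datasets follow
`<root>/<pig>/<day>/frame_%04d.png` + `depth_%04d.tif` + `truth.csv`, with
scale weights in `<root>/weights.csv`. Every pipeline run writes a JSON
manifest (package and R versions, seed, full configuration, MD5 of each
output CSV) sufficient to re-run and byte-compare the outputs.

## Known limitations

* Length is the long side of the bounding box; a strongly bent pig will
  measure short. No midline/spine-curve correction is attempted.
* One animal per frame; no identification or tracking.
* The floor is assumed flat at a known camera height; per-video floor
  re-estimation from the depth map outside the mask is not implemented.
* Heights rely on the depth sensor's accuracy at 2.25 m; real sensors show
  distance-dependent error not captured by the additive noise model.
* Descriptors remain in pixel units; comparisons across camera geometries
  require a calibration this package does not provide.
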