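Package: pigmorph
Title: RGB-D Morphometry and Body-Weight Forecasting for Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts top-view RGB-D video of freely moving pigs into
    morphological image descriptors (body length, width, height and a derived
    volume) and forecasts live body weight one to four days ahead. The image
    pipeline segments the animal by global thresholding, removes the tail by
    morphological opening, fits a minimum-area rotated bounding box to the
    body contour, and reads height from the depth map at the body centroid;
    per-video estimates are medians over quality-controlled frames, with
    k-means separation of standing from sitting postures. Forecasting uses
    random-intercept linear mixed models under a sliding-window time-series
    cross-validation. A synthetic top-view scene generator with known ground
    truth makes every stage testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
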