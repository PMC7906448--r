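#' Single-channel rendering of a depth image for segmentation
#'
#' Two input routes feed the same segmentation as the RGB path: a 3-channel
#' colorized depth rendering is reduced to its HSV hue channel (scaled to
#' 8 bits), while a raw metric depth map is min-max normalized to 8 bits.
#' Either way the animal and the floor end up in well-separated intensity
#' modes that a global threshold can split.
#'
#' @param x Either an H x W x 3 array (colorized depth, 8-bit) or an H x W
#'   numeric matrix of depths in millimeters.
#' @return H x W integer matrix with values in 0..255.
#' @export
depth_to_hue <- function(x) {
  d <- dim(x)
  if (length(d) == 3 && d[3] == 3) {
    hue <- grDevices::rgb2hsv(r = as.vector(x[, , 1]),
                              g = as.vector(x[, , 2]),
                              b = as.vector(x[, , 3]), maxColorValue = 255)[1, ]
    return(matrix(as.integer(round(hue * 255)), d[1], d[2]))
  }
  if (length(d) == 2 || is.matrix(x)) {
    x <- as.matrix(x)
    rng <- range(x)
    if (diff(rng) == 0) return(matrix(0L, nrow(x), ncol(x)))
    matrix(as.integer(round((x - rng[1]) / diff(rng) * 255)), nrow(x), ncol(x))
  } else {
    stop("expected a 3-channel array or a single-channel matrix",
         call. = FALSE)
  }
}

#' Area centroid of a binary mask
#'
#' First image moments divided by the area, rounded half-up to the nearest
#' pixel.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Named integer vector `c(x =, y =)`, 0-based pixel coordinates.
#' @export
centroid_of_mask <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop(no_object_condition("empty mask has no centroid"))
  cx <- mean(idx[, 2]) - 1  # 0-based x = column
  cy <- mean(idx[, 1]) - 1
  c(x = as.integer(floor(cx + 0.5)), y = as.integer(floor(cy + 0.5)))
}

#' Depth at the body centroid
#'
#' Median of the valid (nonzero) depth readings in a
#' `(2 * window_px + 1)^2` neighbourhood of the centroid, converted to
#' meters. A small median window tolerates the invalid (zero) pixels that
#' structured-light sensors scatter over the image.
#'
#' @param depth_mm H x W matrix of depths in millimeters (0 = invalid).
#' @param centroid `c(x, y)` 0-based pixel coordinates.
#' @param window_px Neighbourhood half-width (default 2, i.e. 5 x 5).
#' @return Depth in meters.
#' @export
sample_centroid_depth <- function(depth_mm, centroid, window_px = 2) {
  h <- nrow(depth_mm)
  w <- ncol(depth_mm)
  x <- centroid[[1]]
  y <- centroid[[2]]
  if (x < 0 || x > w - 1 || y < 0 || y > h - 1)
    stop("centroid lies outside the image", call. = FALSE)
  rows <- max(1, y + 1 - window_px):min(h, y + 1 + window_px)
  cols <- max(1, x + 1 - window_px):min(w, x + 1 + window_px)
  vals <- depth_mm[rows, cols]
  vals <- vals[vals > 0]
  if (length(vals) == 0)
    stop(invalid_depth_condition("all depth readings near the centroid are invalid"))
  median(vals) / 1000
}

invalid_depth_condition <- function(msg) {
  structure(class = c("pigmorph_invalid_depth", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Body height from the centroid depth
#'
#' The camera-to-animal distance subtracted from the camera-to-floor
#' distance.
#'
#' @param centroid_depth_m Camera-to-animal distance in meters.
#' @param camera_height_m Camera-to-floor distance in meters (2.25 by
#'   default).
#' @return Height in meters (> 0).
#' @export
height_from_depth <- function(centroid_depth_m, camera_height_m = 2.25) {
  stopifnot(centroid_depth_m > 0)
  h <- camera_height_m - centroid_depth_m
  if (h <= 0)
    stop(invalid_depth_condition("centroid depth at or below the floor"))
  h
}

#' Height of the animal on one depth frame
#'
#' Segments the depth rendering, locates the mask centroid, reads the median
#' depth around it and subtracts from the camera height.
#'
#' @param depth_mm H x W depth matrix in millimeters.
#' @param config A [pipeline_config()].
#' @param frame_index Frame number recorded in the output.
#' @return One-row data frame: `frame`, `qc` (OK / NO_OBJECT /
#'   INVALID_DEPTH), `centroid_x`, `centroid_y`, `centroid_depth_m`,
#'   `height_m`.
#' @export
measure_height_frame <- function(depth_mm, config = pipeline_config(),
                                 frame_index = 1L) {
  row <- function(qc, cx = NA_integer_, cy = NA_integer_, d = NA_real_,
                  hm = NA_real_) {
    data.frame(frame = as.integer(frame_index), qc = qc, centroid_x = cx,
               centroid_y = cy, centroid_depth_m = d, height_m = hm,
               stringsAsFactors = FALSE)
  }
  seg <- tryCatch(
    segment_largest(depth_to_hue(depth_mm), config$opening_diameter_px,
                    config$fixed_threshold, config$auto_polarity),
    pigmorph_no_object = function(e) NULL
  )
  if (is.null(seg)) return(row("NO_OBJECT"))
  ctr <- c(x = as.integer(floor(seg$centroid[["x"]] + 0.5)),
           y = as.integer(floor(seg$centroid[["y"]] + 0.5)))
  out <- tryCatch({
    d <- sample_centroid_depth(depth_mm, ctr, config$centroid_window_px)
    hm <- height_from_depth(d, config$camera_height_m)
    row("OK", ctr[["x"]], ctr[["y"]], d, hm)
  }, pigmorph_invalid_depth = function(e) row("INVALID_DEPTH",
                                              ctr[["x"]], ctr[["y"]]))
  out
}

#' Two-cluster posture separation of per-frame heights
#'
#' One-dimensional 2-means over the height estimates (best of `restarts`
#' seeded starts); the cluster with the higher median is taken as the
#' standing posture. If the cluster means differ by less than `merge_tol`
#' the video is treated as single-posture and the clusters are merged, so
#' videos in which the animal never sits are not split artificially.
#'
#' @param heights Numeric vector of per-frame heights in meters.
#' @param seed Integer seed for the k-means restarts.
#' @param restarts Number of random restarts.
#' @param merge_tol Minimum cluster-mean separation in meters.
#' @return An object of class `posture_clustering`: list with `labels`
#'   (1 = standing cluster, 2 = the other), `cluster_medians` (standing
#'   first), `standing_median`, and `merged`.
#' @export
cluster_postures <- function(heights, seed = 1L, restarts = 10,
                             merge_tol = 0.05) {
  n <- length(heights)
  merged_result <- function() {
    structure(list(labels = rep(1L, n),
                   cluster_medians = c(median(heights), NA_real_),
                   standing_median = median(heights), merged = TRUE),
              class = "posture_clustering")
  }
  if (n < 2 || length(unique(heights)) < 2) return(merged_result())
  if (n == 2) {  # stats::kmeans needs more points than centres
    if (abs(diff(heights)) < merge_tol) return(merged_result())
    labels <- ifelse(heights == max(heights), 1L, 2L)
    return(structure(list(labels = labels,
                          cluster_medians = c(max(heights), min(heights)),
                          standing_median = max(heights), merged = FALSE),
                     class = "posture_clustering"))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  km <- kmeans(matrix(heights, ncol = 1), centers = 2, nstart = restarts)
  if (abs(diff(km$centers[, 1])) < merge_tol) return(merged_result())
  med <- tapply(heights, km$cluster, median)
  standing <- as.integer(names(med)[which.max(med)])
  labels <- ifelse(km$cluster == standing, 1L, 2L)
  structure(list(labels = labels,
                 cluster_medians = c(max(med), min(med)),
                 standing_median = max(med), merged = FALSE),
            class = "posture_clustering")
}

#' Exhaustive 1-D two-cluster partition (reference implementation)
#'
#' Scans every split point of the sorted data and returns the two-segment
#' partition minimizing within-cluster sum of squares. In one dimension the
#' optimal 2-means solution is such a contiguous split, so this serves as an
#' exact oracle for [cluster_postures()] on small samples.
#'
#' @param x Numeric vector, length >= 2.
#' @return List with `labels` (cluster of each value, 1 = lower segment),
#'   `split` (index in sort order after which the split falls), and `wss`.
#' @export
best_split_1d <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  o <- order(x)
  xs <- x[o]
  best <- NULL
  for (k in 1:(n - 1)) {
    lo <- xs[1:k]
    hi <- xs[(k + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || wss < best$wss) best <- list(split = k, wss = wss)
  }
  labels <- integer(n)
  labels[o] <- rep(c(1L, 2L), c(best$split, n - best$split))
  list(labels = labels, split = best$split, wss = best$wss)
}

#' Single height estimate for a video
#'
#' Per-frame heights via segmentation, centroid depth and subtraction; QC
#' failures are dropped; the remaining heights are split into postures and
#' the median of the standing cluster is returned.
#'
#' @param x A `pig_video`, a list of depth matrices (or `frame_pair`s with
#'   `depth_mm`), or a directory containing `depth_%04d.tif` files.
#' @param config A [pipeline_config()].
#' @param seed Seed for the posture clustering.
#' @return List with `height_m`, `n_used`, `merged`, and `frames` (the
#'   per-frame height table).
#' @export
video_height <- function(x, config = pipeline_config(), seed = 1L) {
  depths <- if (inherits(x, "pig_video")) {
    lapply(seq_len(x$n_frames), function(i)
      get_frame(x, i, what = "depth")$depth_mm)
  } else if (is.character(x)) {
    lapply(read_video_frames(x, what = "depth"), `[[`, "depth_mm")
  } else {
    lapply(x, function(f) if (is.list(f)) f$depth_mm else f)
  }
  rows <- do.call(rbind, lapply(seq_along(depths), function(i)
    measure_height_frame(depths[[i]], config, i)))
  ok <- rows[rows$qc == "OK", , drop = FALSE]
  if (nrow(ok) == 0) {
    stop(structure(
      class = c("pigmorph_no_valid_frames", "error", "condition"),
      list(message = "no frame yielded a valid height", call = NULL)
    ))
  }
  cl <- cluster_postures(ok$height_m, seed = seed,
                         restarts = config$kmeans_restarts,
                         merge_tol = config$kmeans_merge_tol)
  standing <- ok$height_m[cl$labels == 1L]
  list(height_m = median(standing), n_used = nrow(ok), merged = cl$merged,
       frames = rows)
}
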