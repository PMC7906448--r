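#' Convert an RGB frame to 8-bit grayscale
#'
#' Standard luminance weighting: `0.299 R + 0.587 G + 0.114 B`, rounded to
#' integers.
#'
#' @param rgb H x W x 3 array of 8-bit values.
#' @return H x W integer matrix.
#' @export
to_grayscale <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an H x W x 3 array", call. = FALSE)
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(as.integer(round(g)), d[1], d[2])
}

qc_levels <- c("OK", "NO_OBJECT", "BORDER_ATTACHED", "AREA_OUT_OF_RANGE")

#' Segment the largest object in a grayscale frame
#'
#' Binarizes the image with a global threshold (Otsu by default), keeps the
#' largest 8-connected component, applies a morphological opening with a
#' Euclidean disc (removing thin protrusions such as the tail), and
#' re-extracts the largest component. The foreground polarity is chosen
#' automatically as the side of the threshold whose largest component covers
#' less than half the frame, so the animal may be lighter or darker than the
#' floor.
#'
#' @param gray H x W integer matrix of 8-bit values.
#' @param opening_diameter Diameter in pixels of the disc structuring
#'   element (the opening uses a Euclidean disc of radius
#'   `(opening_diameter - 1) / 2`).
#' @param threshold Fixed threshold overriding Otsu, or `NULL`.
#' @param auto_polarity Choose the foreground side automatically; if
#'   `FALSE`, foreground is `gray > threshold`.
#' @return An object of class `segmentation`: list with `mask` (logical
#'   H x W), `area_px`, `contour` (ordered n x 2 matrix of 0-based (x, y)
#'   boundary points), `centroid` (unrounded), and `threshold`; or a
#'   `pigmorph_no_object` condition is signalled if nothing remains.
#' @export
segment_largest <- function(gray, opening_diameter = 15, threshold = NULL,
                            auto_polarity = TRUE) {
  if (!is.matrix(gray)) stop("expected a single-channel matrix", call. = FALSE)
  radius <- (opening_diameter - 1) / 2
  res <- segment_largest_cpp(
    matrix(as.integer(gray), nrow(gray), ncol(gray)), radius,
    if (is.null(threshold)) -1L else as.integer(threshold), auto_polarity
  )
  if (!isTRUE(res$found)) {
    stop(no_object_condition("no foreground object after opening"))
  }
  structure(
    list(mask = res$mask, area_px = res$area, contour = res$contour,
         centroid = c(x = res$centroid_x, y = res$centroid_y),
         threshold = res$threshold,
         bright_foreground = res$bright_foreground),
    class = "segmentation"
  )
}

no_object_condition <- function(msg) {
  structure(class = c("pigmorph_no_object", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Minimum-area rotated bounding box of a contour
#'
#' Exact rotating-calipers search over the convex hull: the optimal
#' rectangle has a side collinear with a hull edge. Sides are reported under
#' the pixel-footprint convention (point extent plus one pixel), so the box
#' of an axis-aligned rectangle of w x h pixels has sides exactly w and h.
#'
#' @param contour n x 2 matrix of (x, y) points, n >= 3, not all collinear.
#' @return An object of class `rotated_box`: list with `center`, `side_a`,
#'   `side_b`, `angle` (degrees in `[0, 180)`, direction of `side_a`), and
#'   `corners` (4 x 2 matrix).
#' @export
rotated_box <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("contour needs at least 3 points", call. = FALSE)
  res <- min_area_rect_cpp(contour[, 1:2, drop = FALSE], 1.0)
  if (!isTRUE(res$ok))
    stop("degenerate contour: points are collinear", call. = FALSE)
  structure(
    list(center = c(x = res$center_x, y = res$center_y), side_a = res$side_a,
         side_b = res$side_b, angle = res$angle, corners = res$corners),
    class = "rotated_box"
  )
}

#' Canonical (length, width) of a rotated box
#'
#' The longer box side is reported as body length, the shorter as width.
#'
#' @param box A [rotated_box()].
#' @return Named numeric vector `c(length_px =, width_px =)`.
#' @export
canonical_length_width <- function(box) {
  stopifnot(inherits(box, "rotated_box"))
  c(length_px = max(box$side_a, box$side_b),
    width_px = min(box$side_a, box$side_b))
}

#' Is a bounding box attached to the image border?
#'
#' `TRUE` if any box corner lies within `margin_px` of an image edge or
#' outside the image; such frames are discarded because part of the animal
#' may be cut off by the fence.
#'
#' @param box A [rotated_box()].
#' @param image_dims `c(height, width)` in pixels.
#' @param margin_px Margin in pixels (default 2).
#' @return Logical scalar.
#' @export
border_attached <- function(box, image_dims, margin_px = 2) {
  stopifnot(inherits(box, "rotated_box"), length(image_dims) >= 2)
  h <- image_dims[1]
  w <- image_dims[2]
  x <- box$corners[, 1]
  y <- box$corners[, 2]
  any(x < margin_px | x > (w - 1) - margin_px |
      y < margin_px | y > (h - 1) - margin_px)
}

#' Is a segmented area plausible for a single animal?
#'
#' @param area_px Foreground pixel count.
#' @param min_frac,max_frac Allowed area as a fraction of the frame.
#' @param image_dims `c(height, width)`.
#' @return Logical scalar.
#' @export
area_in_range <- function(area_px, min_frac = 0.01, max_frac = 0.40,
                          image_dims = c(480, 848)) {
  stopifnot(min_frac >= 0, min_frac < max_frac, max_frac <= 1)
  npix <- as.numeric(image_dims[1]) * image_dims[2]
  area_px >= min_frac * npix & area_px <= max_frac * npix
}

#' Measure body length and width on one frame
#'
#' Runs the full single-frame chain: grayscale conversion, threshold
#' segmentation with tail-removing opening, minimum-area rotated box, then
#' quality control (border attachment first, then the area range). Frames
#' failing any step carry the reason in `qc` and no measurements.
#'
#' @param frame A `frame_pair` (or any list with an `rgb` array).
#' @param config A [pipeline_config()].
#' @return One-row data frame: `frame`, `qc`
#'   (OK / NO_OBJECT / BORDER_ATTACHED / AREA_OUT_OF_RANGE), `length_px`,
#'   `width_px`, `area_px`.
#' @export
measure_frame <- function(frame, config = pipeline_config()) {
  gray <- to_grayscale(frame$rgb)
  dims <- dim(gray)
  row <- function(qc, len = NA_real_, wid = NA_real_, area = NA_real_) {
    data.frame(frame = as.integer(frame$frame_index %||% 1L), qc = qc,
               length_px = len, width_px = wid, area_px = area,
               stringsAsFactors = FALSE)
  }
  seg <- tryCatch(
    segment_largest(gray, config$opening_diameter_px,
                    config$fixed_threshold, config$auto_polarity),
    pigmorph_no_object = function(e) NULL
  )
  if (is.null(seg) || nrow(seg$contour) < 3) return(row("NO_OBJECT"))
  box <- tryCatch(rotated_box(seg$contour), error = function(e) NULL)
  if (is.null(box)) return(row("NO_OBJECT", area = seg$area_px))
  if (border_attached(box, dims, config$border_margin_px))
    return(row("BORDER_ATTACHED", area = seg$area_px))
  if (!area_in_range(seg$area_px, config$min_area_frac, config$max_area_frac,
                     dims))
    return(row("AREA_OUT_OF_RANGE", area = seg$area_px))
  lw <- canonical_length_width(box)
  row("OK", lw[["length_px"]], lw[["width_px"]], seg$area_px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure every frame of a video
#'
#' For a lazily simulated `pig_video` the render-and-measure loop runs in
#' compiled code without materializing frames; for a list of `frame_pair`s
#' or a directory of PNG frames, [measure_frame()] is applied per frame.
#' Both paths share the same kernels and produce identical measurements on
#' identical frames.
#'
#' @param x A `pig_video`, a list of `frame_pair`s, or a directory path
#'   containing `frame_%04d.png` files.
#' @param config A [pipeline_config()].
#' @return Data frame with one row per frame: `frame`, `qc`, `length_px`,
#'   `width_px`, `area_px`.
#' @export
measure_video <- function(x, config = pipeline_config()) {
  UseMethod("measure_video")
}

#' @export
measure_video.pig_video <- function(x, config = pipeline_config()) {
  cfg <- x$cfg
  tr <- x$truth
  radius <- (config$opening_diameter_px - 1) / 2
  out <- measure_sim_video_cpp(
    cfg$image_width, cfg$image_height, tr$center_x, tr$center_y,
    tr$orientation, tr$true_length, tr$true_width, tr$blurred, tr$blur_angle,
    cfg$blur_length_px, cfg$pig_gray, cfg$floor_gray, cfg$tail_length_px,
    cfg$tail_width_px, radius,
    if (is.null(config$fixed_threshold)) -1L
    else as.integer(config$fixed_threshold),
    config$auto_polarity, config$border_margin_px, config$min_area_frac,
    config$max_area_frac
  )
  out$qc <- qc_levels[out$qc + 1L]
  out
}

#' @export
measure_video.list <- function(x, config = pipeline_config()) {
  out <- do.call(rbind, lapply(x, measure_frame, config = config))
  rownames(out) <- NULL
  out
}

#' @export
measure_video.character <- function(x, config = pipeline_config()) {
  frames <- read_video_frames(x, what = "rgb")
  measure_video.list(frames, config)
}

#' Aggregate per-frame measurements into per-video estimates
#'
#' Medians of length and width over the frames that passed quality control;
#' the median keeps single-video estimates robust to residual shape
#' distortion and motion blur among the retained frames.
#'
#' @param measurements Data frame from [measure_video()].
#' @return List with `median_length_px`, `median_width_px`, `n_used`.
#' @export
aggregate_length_width <- function(measurements) {
  ok <- measurements[measurements$qc == "OK", , drop = FALSE]
  if (nrow(ok) == 0) {
    stop(structure(
      class = c("pigmorph_no_valid_frames", "error", "condition"),
      list(message = "no frame passed quality control", call = NULL)
    ))
  }
  list(median_length_px = median(ok$length_px),
       median_width_px = median(ok$width_px), n_used = nrow(ok))
}
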