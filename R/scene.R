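#' Scene configuration for the synthetic top-view generator
#'
#' Describes one synthetic recording session: image geometry, camera height,
#' the animal's true size, and the mixture of frame conditions. Defaults
#' reproduce the acquisition setup the pipeline targets: a ceiling-mounted
#' RGB-D camera 2.25 m above the pen floor recording 848 x 480 frames.
#'
#' The rendered animal is a filled rotated ellipse (axes `pig_length` x
#' `pig_width`) with a thin tail rectangle appended at one pole, so the
#' tail-removal step of the measurement pipeline is exercised. Sitting frames
#' scale the body height by `sitting_scale`. The depth surface equals
#' `floor_depth_mm` on the floor and tapers from the full body height at the
#' ellipse centre to 70% of it at the outline, so the centroid depth recovers
#' the nominal height exactly on noiseless frames.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param camera_height Camera-to-floor distance in meters.
#' @param floor_depth_mm Floor depth in millimeters; must equal
#'   `round(1000 * camera_height)`.
#' @param pig_length,pig_width True body axes in pixels (`pig_length >=
#'   pig_width > 0`).
#' @param pig_height True standing body height in meters.
#' @param standing_fraction Probability that a frame shows a standing animal.
#' @param border_fraction,blur_fraction Probabilities that a frame is
#'   border-touching or motion-blurred (mutually exclusive conditions;
#'   their sum must not exceed 1).
#' @param depth_noise_sd Additive depth noise standard deviation in
#'   millimeters (Gaussian, truncated at four standard deviations).
#' @param sitting_scale Height multiplier for sitting frames.
#' @param tail_length_px,tail_width_px Tail rectangle size in pixels; the
#'   tail must be thinner than the opening kernel that removes it.
#' @param blur_length_px Length of the directional motion-blur kernel.
#' @param pig_gray,floor_gray 8-bit intensities of animal and floor.
#' @param rng_seed Integer seed used when the config itself is asked to
#'   generate randomness.
#'
#' @return An object of class `scene_config`.
#' @seealso [simulate_video()], [render_frame()]
#' @export
scene_config <- function(image_width = 848L, image_height = 480L,
                         camera_height = 2.25, floor_depth_mm = 2250L,
                         pig_length = 200, pig_width = 84,
                         pig_height = 0.5, standing_fraction = 0.7,
                         border_fraction = 0.2, blur_fraction = 0.1,
                         depth_noise_sd = 5, sitting_scale = 0.55,
                         tail_length_px = 35, tail_width_px = 5,
                         blur_length_px = 15, pig_gray = 180L,
                         floor_gray = 70L, rng_seed = 1L) {
  cfg <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    camera_height = camera_height, floor_depth_mm = as.integer(floor_depth_mm),
    pig_length = pig_length, pig_width = pig_width, pig_height = pig_height,
    standing_fraction = standing_fraction,
    border_fraction = border_fraction, blur_fraction = blur_fraction,
    depth_noise_sd = depth_noise_sd, sitting_scale = sitting_scale,
    tail_length_px = tail_length_px, tail_width_px = tail_width_px,
    blur_length_px = blur_length_px, pig_gray = as.integer(pig_gray),
    floor_gray = as.integer(floor_gray), rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$image_width > 0, cfg$image_height > 0)
  if (!(cfg$pig_length >= cfg$pig_width && cfg$pig_width > 0))
    stop("pig_length >= pig_width > 0 is required", call. = FALSE)
  fr <- c(cfg$standing_fraction, cfg$border_fraction, cfg$blur_fraction)
  if (any(fr < 0 | fr > 1))
    stop("frame-condition fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$border_fraction + cfg$blur_fraction > 1)
    stop("border_fraction + blur_fraction must not exceed 1", call. = FALSE)
  if (cfg$floor_depth_mm != round(1000 * cfg$camera_height))
    stop("floor_depth_mm must equal round(1000 * camera_height)", call. = FALSE)
  if (cfg$pig_height <= 0 || cfg$pig_height >= cfg$camera_height)
    stop("pig_height must lie in (0, camera_height)", call. = FALSE)
  if (cfg$depth_noise_sd < 0) stop("depth_noise_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Per-frame ground truth for a synthetic frame
#'
#' @param frame_index Frame number (1-based).
#' @param center Numeric `(x, y)` body centre in pixels (0-based, must lie
#'   inside the image).
#' @param orientation Major-axis angle in degrees, in `[0, 180)`.
#' @param posture `"standing"` or `"sitting"`.
#' @param touches_border Does the body cross an image edge?
#' @param blurred Is the frame motion-blurred?
#' @param true_length,true_width True body axes in pixels.
#' @param true_height True standing height in meters.
#' @param blur_angle Direction of the motion blur in degrees.
#'
#' @return A one-row `data.frame` of class `frame_truth`.
#' @export
frame_truth <- function(frame_index = 1L, center = c(424, 240),
                        orientation = 0, posture = "standing",
                        touches_border = FALSE, blurred = FALSE,
                        true_length = 200, true_width = 84,
                        true_height = 0.5, blur_angle = 0) {
  stopifnot(true_length >= true_width, true_width > 0, true_height > 0,
            posture %in% c("standing", "sitting"))
  orientation <- orientation %% 180
  out <- data.frame(
    frame_index = as.integer(frame_index), center_x = center[1],
    center_y = center[2], orientation = orientation, posture = posture,
    touches_border = touches_border, blurred = blurred,
    true_length = true_length, true_width = true_width,
    true_height = true_height, blur_angle = blur_angle,
    stringsAsFactors = FALSE
  )
  class(out) <- c("frame_truth", "data.frame")
  out
}

# Axis-aligned half-extents of a rotated ellipse.
ellipse_extents <- function(a, b, theta_deg) {
  th <- theta_deg * pi / 180
  c(
    x = sqrt((a * cos(th))^2 + (b * sin(th))^2),
    y = sqrt((a * sin(th))^2 + (b * cos(th))^2)
  )
}

#' Render one synthetic RGB-D frame
#'
#' Draws the animal described by `truth` onto a uniform floor: an 8-bit RGB
#' frame (equal channels) plus a 16-bit metric depth map in millimeters.
#' The depth map equals `floor_depth_mm` outside the animal and
#' `floor_depth_mm - round(1000 * h * profile)` inside it, where `h` is the
#' effective body height (scaled by `sitting_scale` for sitting frames) and
#' the profile tapers from 1 at the body centre to 0.7 at the outline.
#' Depth noise and motion blur are applied according to the config/truth.
#'
#' @param cfg A [scene_config()].
#' @param truth A [frame_truth()] row.
#' @return A `frame_pair`: list with `rgb` (H x W x 3 integer array),
#'   `depth_mm` (H x W integer matrix) and `frame_index`.
#' @export
render_frame <- function(cfg, truth) {
  validate_scene_config(cfg)
  t1 <- as.list(truth[1, , drop = FALSE])
  w <- cfg$image_width
  h <- cfg$image_height
  if (t1$center_x < 0 || t1$center_x > w - 1 ||
      t1$center_y < 0 || t1$center_y > h - 1)
    stop("truth center must lie inside the image", call. = FALSE)
  if (!isTRUE(t1$touches_border)) {
    ext <- ellipse_extents(t1$true_length / 2, t1$true_width / 2,
                           t1$orientation)
    reach <- ext + cfg$tail_length_px
    if (t1$center_x - reach["x"] < 0 || t1$center_x + reach["x"] > w - 1 ||
        t1$center_y - reach["y"] < 0 || t1$center_y + reach["y"] > h - 1)
      stop("ellipse does not fit the frame for a non-border truth",
           call. = FALSE)
  }
  posture_scale <- if (identical(t1$posture, "sitting")) cfg$sitting_scale else 1
  res <- render_scene_cpp(
    w, h, t1$center_x, t1$center_y, t1$orientation, t1$true_length,
    t1$true_width, t1$true_height, posture_scale, isTRUE(t1$blurred),
    cfg$blur_length_px, t1$blur_angle, cfg$floor_depth_mm, cfg$depth_noise_sd,
    cfg$pig_gray, cfg$floor_gray, cfg$tail_length_px, cfg$tail_width_px, TRUE
  )
  frame_pair(array(res$gray, c(h, w, 3)), res$depth, t1$frame_index)
}

#' Construct a frame pair (RGB image plus aligned depth map)
#'
#' @param rgb H x W x 3 integer array with 8-bit values.
#' @param depth_mm H x W integer matrix of metric depths in millimeters
#'   (0 marks an invalid pixel), or `NULL` for RGB-only records.
#' @param frame_index Frame number.
#' @return A list of class `frame_pair`.
#' @export
frame_pair <- function(rgb, depth_mm = NULL, frame_index = 1L) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (!is.null(depth_mm)) {
    stopifnot(all(dim(rgb)[1:2] == dim(depth_mm)),
              min(depth_mm) >= 0, max(depth_mm) <= 65535)
  }
  structure(list(rgb = rgb, depth_mm = depth_mm,
                 frame_index = as.integer(frame_index)),
            class = "frame_pair")
}

#' Simulate a synthetic top-view video
#'
#' Draws per-frame ground truths i.i.d. from the mixture in `cfg` (posture
#' standing with probability `standing_fraction`; border-touching and blurred
#' frames with their respective probabilities, mutually exclusive), with
#' uniform interior positions and orientations. Border-touching frames place
#' the body centre within `0.8 * pig_width / 2` of a randomly chosen edge so
#' the body is guaranteed to cross it.
#'
#' Frames are rendered lazily: the returned object stores the truth table and
#' one RNG sub-seed per frame, and [get_frame()] renders any frame
#' reproducibly on demand. Two videos simulated with the same seed are
#' therefore bitwise identical, frame payloads included.
#'
#' @param cfg A [scene_config()].
#' @param n_frames Number of frames (a 3-minute recording at 6 frames/s is
#'   1080 frames).
#' @param seed Integer master seed for this video.
#' @return An object of class `pig_video` with elements `cfg`, `truth`
#'   (one row per frame), `frame_seeds` and `n_frames`.
#' @export
simulate_video <- function(cfg, n_frames, seed = 1L) {
  validate_scene_config(cfg)
  stopifnot(n_frames >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  w <- cfg$image_width
  h <- cfg$image_height
  a <- cfg$pig_length / 2
  b <- cfg$pig_width / 2
  reach <- a + cfg$tail_length_px + 2
  n <- as.integer(n_frames)

  u <- runif(n)
  touches <- u < cfg$border_fraction
  blurred <- !touches & u < cfg$border_fraction + cfg$blur_fraction
  posture <- ifelse(runif(n) < cfg$standing_fraction, "standing", "sitting")
  orientation <- runif(n, 0, 180)
  blur_angle <- runif(n, 0, 360)

  cx <- runif(n, min(reach, (w - 1) / 2), max((w - 1) - reach, (w - 1) / 2))
  cy <- runif(n, min(reach, (h - 1) / 2), max((h - 1) - reach, (h - 1) / 2))
  nb <- sum(touches)
  if (nb > 0) {
    edge <- sample(4, nb, replace = TRUE)
    d <- runif(nb, 0, 0.8 * b)  # body contains a disc of radius b => crosses
    cx[touches] <- ifelse(edge == 1, d,
                   ifelse(edge == 2, (w - 1) - d, cx[touches]))
    cy[touches] <- ifelse(edge == 3, d,
                   ifelse(edge == 4, (h - 1) - d, cy[touches]))
  }
  truth <- data.frame(
    frame_index = seq_len(n), center_x = cx, center_y = cy,
    orientation = orientation, posture = posture, touches_border = touches,
    blurred = blurred, true_length = cfg$pig_length,
    true_width = cfg$pig_width, true_height = cfg$pig_height,
    blur_angle = blur_angle, stringsAsFactors = FALSE
  )
  frame_seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
  structure(list(cfg = cfg, truth = truth, frame_seeds = frame_seeds,
                 n_frames = n),
            class = "pig_video")
}

#' Render one frame of a simulated video
#'
#' @param video A `pig_video` from [simulate_video()].
#' @param i Frame index (1-based).
#' @param what Channels to render: any of `"rgb"`, `"depth"`.
#' @return A `frame_pair`; `depth_mm` is `NULL` when depth is not requested.
#' @export
get_frame <- function(video, i, what = c("rgb", "depth")) {
  stopifnot(inherits(video, "pig_video"), i >= 1, i <= video$n_frames)
  what <- match.arg(what, several.ok = TRUE)
  cfg <- video$cfg
  t1 <- as.list(video$truth[i, , drop = FALSE])
  old <- local_seed(video$frame_seeds[i])
  on.exit(restore_seed(old), add = TRUE)
  posture_scale <- if (identical(t1$posture, "sitting")) cfg$sitting_scale else 1
  res <- render_scene_cpp(
    cfg$image_width, cfg$image_height, t1$center_x, t1$center_y,
    t1$orientation, t1$true_length, t1$true_width, t1$true_height,
    posture_scale, isTRUE(t1$blurred), cfg$blur_length_px, t1$blur_angle,
    cfg$floor_depth_mm, cfg$depth_noise_sd, cfg$pig_gray, cfg$floor_gray,
    cfg$tail_length_px, cfg$tail_width_px, "depth" %in% what
  )
  rgb <- array(res$gray, c(cfg$image_height, cfg$image_width, 3))
  frame_pair(rgb, if ("depth" %in% what) res$depth else NULL, i)
}

#' Number of frames in a recording
#'
#' @param duration_s Recording length in seconds (default 180, i.e. the
#'   3-minute daily recordings the pipeline is sized for).
#' @param fps Frame rate (default 6 frames per second).
#' @return Integer frame count (1080 under the defaults).
#' @export
recording_frame_count <- function(duration_s = 180, fps = 6) {
  stopifnot(duration_s > 0, fps > 0)
  as.integer(round(duration_s * fps))
}

# Seed handling: run a block under a given seed, then restore the caller's
# RNG state so library code does not clobber user randomness.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive bounded sub-seeds from a master seed (kept below 2^31).
derive_seeds <- function(master, n) {
  old <- local_seed(master)
  on.exit(restore_seed(old), add = TRUE)
  sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
}
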