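#' Pipeline configuration
#'
#' All tunable constants of the measurement and forecasting pipeline in one
#' validated object. Defaults reproduce the acquisition and analysis setup
#' the pipeline was designed for: 848 x 480 frames, a camera 2.25 m above
#' the floor, a 14-day training window and 1-4 day forecast horizons.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param camera_height_m Camera-to-floor distance in meters.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold 8-bit threshold used when `threshold_method` is
#'   `"fixed"`, otherwise `NULL`.
#' @param auto_polarity Pick the foreground side of the threshold
#'   automatically.
#' @param opening_diameter_px Diameter of the disc structuring element of
#'   the tail-removing morphological opening.
#' @param border_margin_px Margin for the border-attachment test.
#' @param min_area_frac,max_area_frac Plausible animal area as fractions of
#'   the frame.
#' @param centroid_window_px Half-width of the centroid depth median
#'   window.
#' @param kmeans_restarts Restarts of the posture 2-means.
#' @param kmeans_merge_tol Cluster-merge tolerance in meters.
#' @param window_days Training-window length for cross-validation.
#' @param horizons Forecast horizons in days.
#' @param r2_method `"cor"` (squared correlation) or `"ssr"` (1 - SSE/SST).
#' @param seed Master seed for the pipeline run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(image_width = 848L, image_height = 480L,
                            camera_height_m = 2.25,
                            threshold_method = "otsu", fixed_threshold = NULL,
                            auto_polarity = TRUE, opening_diameter_px = 15,
                            border_margin_px = 2, min_area_frac = 0.01,
                            max_area_frac = 0.40, centroid_window_px = 2,
                            kmeans_restarts = 10, kmeans_merge_tol = 0.05,
                            window_days = 14L, horizons = 1:4,
                            r2_method = "cor", seed = 1L) {
  cfg <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    camera_height_m = camera_height_m, threshold_method = threshold_method,
    fixed_threshold = fixed_threshold, auto_polarity = auto_polarity,
    opening_diameter_px = opening_diameter_px,
    border_margin_px = border_margin_px, min_area_frac = min_area_frac,
    max_area_frac = max_area_frac, centroid_window_px = centroid_window_px,
    kmeans_restarts = kmeans_restarts, kmeans_merge_tol = kmeans_merge_tol,
    window_days = as.integer(window_days), horizons = as.integer(horizons),
    r2_method = r2_method, seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  fail <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) fail <<- c(fail, msg)
  chk(cfg$image_width > 0 && cfg$image_height > 0,
      "image dimensions must be positive")
  chk(cfg$camera_height_m > 0, "camera_height_m must be positive")
  chk(cfg$threshold_method %in% c("otsu", "fixed"),
      "threshold_method must be 'otsu' or 'fixed'")
  if (identical(cfg$threshold_method, "fixed"))
    chk(!is.null(cfg$fixed_threshold) && cfg$fixed_threshold >= 0 &&
          cfg$fixed_threshold <= 255,
        "fixed_threshold must be in 0..255 when threshold_method = 'fixed'")
  chk(cfg$opening_diameter_px >= 1, "opening_diameter_px must be >= 1")
  chk(cfg$border_margin_px >= 0, "border_margin_px must be >= 0")
  chk(cfg$min_area_frac >= 0 && cfg$min_area_frac < cfg$max_area_frac &&
        cfg$max_area_frac <= 1,
      "need 0 <= min_area_frac < max_area_frac <= 1")
  chk(cfg$centroid_window_px >= 0, "centroid_window_px must be >= 0")
  chk(cfg$kmeans_restarts >= 1, "kmeans_restarts must be >= 1")
  chk(cfg$kmeans_merge_tol >= 0, "kmeans_merge_tol must be >= 0")
  chk(cfg$window_days >= 2, "window_days must be >= 2")
  chk(length(cfg$horizons) >= 1 && all(cfg$horizons >= 1),
      "horizons must be positive integers")
  chk(cfg$r2_method %in% c("cor", "ssr"), "r2_method must be 'cor' or 'ssr'")
  if (length(fail))
    stop("invalid pipeline configuration:\n  - ",
         paste(fail, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' unknown keys are rejected; the merged configuration is validated with
#' explicit error messages. An empty file yields all defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Save a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
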