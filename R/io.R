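#' Write one frame pair to disk
#'
#' RGB frames are written as 8-bit PNG; depth maps as 16-bit grayscale TIFF
#' holding millimeters (losslessly, exact integer round-trip).
#'
#' @param frame A `frame_pair`.
#' @param dir Output directory (created if needed).
#' @param index Frame number used in the file names
#'   (`frame_%04d.png`, `depth_%04d.tif`).
#' @return Invisibly, the paths written.
#' @export
write_frame_pair <- function(frame, dir, index = frame$frame_index) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rgb_path <- file.path(dir, sprintf("frame_%04d.png", index))
  png::writePNG(frame$rgb / 255, rgb_path)
  paths <- rgb_path
  if (!is.null(frame$depth_mm)) {
    depth_path <- file.path(dir, sprintf("depth_%04d.tif", index))
    tiff::writeTIFF(frame$depth_mm / 65535, depth_path, bits.per.sample = 16,
                    compression = "LZW")
    paths <- c(paths, depth_path)
  }
  invisible(paths)
}

#' Read the frames of one video directory
#'
#' @param dir Directory containing `frame_%04d.png` and optionally
#'   `depth_%04d.tif` files.
#' @param what Channels to read.
#' @return List of `frame_pair`s in frame order. Unreadable files are
#'   skipped with a warning.
#' @export
read_video_frames <- function(dir, what = c("rgb", "depth")) {
  what <- match.arg(what, several.ok = TRUE)
  rgbs <- sort(list.files(dir, "^frame_\\d+\\.png$", full.names = TRUE))
  deps <- sort(list.files(dir, "^depth_\\d+\\.tif$", full.names = TRUE))
  if ("rgb" %in% what && length(rgbs) == 0)
    stop("no RGB frames (frame_NNNN.png) found in ", dir, call. = FALSE)
  if (identical(what, "depth") && length(deps) == 0)
    stop("no depth frames (depth_NNNN.tif) found in ", dir, call. = FALSE)
  n <- if ("rgb" %in% what) length(rgbs) else length(deps)
  out <- vector("list", n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    fp <- tryCatch({
      rgb <- if ("rgb" %in% what) {
        arr <- png::readPNG(rgbs[i])
        if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 3))
        array(as.integer(round(arr[, , 1:3] * 255)), c(dim(arr)[1:2], 3))
      } else NULL
      depth <- NULL
      if ("depth" %in% what && length(deps) >= i) {
        d <- tiff::readTIFF(deps[i], as.is = TRUE)
        depth <- matrix(as.integer(d), nrow(d), ncol(d))
      }
      if (is.null(rgb)) {
        h <- nrow(depth)
        w <- ncol(depth)
        rgb <- array(0L, c(h, w, 3))
      }
      frame_pair(rgb, depth, i)
    }, error = function(e) {
      warning("skipping unreadable frame ", i, " in ", dir, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(fp)) {
      out[[i]] <- fp
      kept[i] <- TRUE
    }
  }
  out[kept]
}

#' Simulate a full multi-day study with known ground truth
#'
#' Couples the longitudinal growth generator to the scene generator: each
#' animal-day gets one video whose true body axes and height come from that
#' day's simulated descriptors, plus a scale weight from the growth model.
#' All randomness fans out from `seed`.
#'
#' @param g A [growth_config()].
#' @param frames_per_video Frames per pig-day video.
#' @param scene A template [scene_config()] supplying everything except the
#'   per-day body size.
#' @param seed Master seed.
#' @return An object of class `pig_study`: list with `records` (list of
#'   `pig_id`, `day`, `video`), `weights`, `truth` (the growth table), and
#'   `params`.
#' @export
simulate_study <- function(g = growth_config(), frames_per_video = 60,
                           scene = scene_config(), seed = 1L) {
  sim <- simulate_growth(g, seed = derive_seeds(seed, 1))
  tab <- sim$table
  vid_seeds <- derive_seeds(seed + 1L, nrow(tab))
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cfg <- scene
    cfg$pig_length <- tab$length_px[i]
    cfg$pig_width <- tab$width_px[i]
    cfg$pig_height <- tab$height_m[i]
    validate_scene_config(cfg)
    records[[i]] <- list(
      pig_id = tab$pig_id[i], day = tab$day[i],
      video = simulate_video(cfg, frames_per_video, seed = vid_seeds[i])
    )
  }
  weights <- tab[, c("pig_id", "day", "weight_kg")]
  structure(list(records = records, weights = weights, truth = tab,
                 params = sim$params),
            class = "pig_study")
}

#' Write a simulated study to disk in the standard dataset layout
#'
#' Layout: `<root>/<pig>/<day>/frame_%04d.png` + `depth_%04d.tif` +
#' `truth.csv`, with `<root>/weights.csv` holding the scale records.
#'
#' @param study A [simulate_study()] result.
#' @param root Output directory.
#' @return `root`, invisibly.
#' @export
write_study <- function(study, root) {
  stopifnot(inherits(study, "pig_study"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (rec in study$records) {
    dir <- file.path(root, rec$pig_id, sprintf("day%02d", rec$day))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(rec$video$n_frames)) {
      write_frame_pair(get_frame(rec$video, i), dir, i)
    }
    write.csv(rec$video$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  write.csv(study$weights, file.path(root, "weights.csv"), row.names = FALSE)
  invisible(root)
}

#' Enumerate the videos of an on-disk dataset
#'
#' @param root Dataset root with the `<root>/<pig>/<day>/` layout.
#' @return Data frame with `pig_id`, `day`, `dir`, `has_depth`, sorted by
#'   pig and day.
#' @export
read_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root, call. = FALSE)
  pig_dirs <- list.dirs(root, recursive = FALSE)
  rows <- list()
  for (pd in pig_dirs) {
    for (dd in list.dirs(pd, recursive = FALSE)) {
      n_rgb <- length(list.files(dd, "^frame_\\d+\\.png$"))
      n_dep <- length(list.files(dd, "^depth_\\d+\\.tif$"))
      if (n_rgb == 0 && n_dep == 0) next
      if (n_rgb == 0)
        stop("video ", dd, " has depth frames but no RGB frames",
             call. = FALSE)
      day <- as.integer(gsub("\\D", "", basename(dd)))
      rows[[length(rows) + 1]] <- data.frame(
        pig_id = basename(pd), day = day, dir = dd, has_depth = n_dep > 0,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) stop("no videos found under ", root, call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$pig_id, out$day), ]
  rownames(out) <- NULL
  out
}
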