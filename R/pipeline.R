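#' Run the full measurement and forecasting pipeline
#'
#' End-to-end composition: per pig-day video, median length/width over
#' QC-passing RGB frames and the standing-cluster height from the depth
#' frames; descriptors joined with the scale weights; the descriptor
#' correlation matrix; and sliding-window cross-validated weight
#' forecasting. All outputs are written as CSV next to a JSON run manifest
#' (configuration, seed, versions, output checksums), so a run can be
#' reproduced and byte-checked.
#'
#' @param x A `pig_study` from [simulate_study()], or the root directory of
#'   an on-disk dataset (see [read_dataset()]; weights are read from
#'   `<root>/weights.csv`).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the assembled `table`, the correlation
#'   matrix, the `forecast` results and `out_dir`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir) {
  UseMethod("run_pipeline")
}

pipeline_video_rows <- function(ids, measure_fun, height_fun, config) {
  m_rows <- list()
  h_rows <- list()
  for (i in seq_len(nrow(ids))) {
    pig <- ids$pig_id[i]
    day <- ids$day[i]
    tag <- sprintf("%s day %s", pig, day)
    agg <- tryCatch(aggregate_length_width(measure_fun(i)),
                    pigmorph_no_valid_frames = function(e) NULL)
    if (is.null(agg)) {
      message("measurement: no valid frames for ", tag, "; video dropped")
    } else {
      m_rows[[length(m_rows) + 1]] <- data.frame(
        pig_id = pig, day = day, length_px = agg$median_length_px,
        width_px = agg$median_width_px, n_frames_used = agg$n_used,
        stringsAsFactors = FALSE
      )
    }
    hv <- tryCatch(height_fun(i),
                   pigmorph_no_valid_frames = function(e) NULL)
    if (is.null(hv)) {
      message("height: no valid frames for ", tag, "; video dropped")
    } else if (!is.null(hv$height_m)) {
      h_rows[[length(h_rows) + 1]] <- data.frame(
        pig_id = pig, day = day, height_m = hv$height_m,
        n_frames_used = hv$n_used, posture_merged = hv$merged,
        stringsAsFactors = FALSE
      )
    }
  }
  list(measurements = do.call(rbind, m_rows), heights = do.call(rbind, h_rows))
}

pipeline_core <- function(ids, measure_fun, height_fun, weights, config,
                          out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  parts <- pipeline_video_rows(ids, measure_fun, height_fun, config)
  if (is.null(parts$measurements) || is.null(parts$heights))
    stop("pipeline produced no usable videos", call. = FALSE)
  descriptors <- merge(parts$measurements[, c("pig_id", "day", "length_px",
                                              "width_px")],
                       parts$heights[, c("pig_id", "day", "height_m")],
                       by = c("pig_id", "day"))
  tab <- join_records(descriptors, weights)
  corr <- pearson_matrix(tab)
  cv <- run_cv(tab, window_days = config$window_days,
               horizons = config$horizons, r2_method = config$r2_method)
  cv_sum <- summary(cv)

  paths <- c(
    measurements = file.path(out_dir, "measurements.csv"),
    heights = file.path(out_dir, "heights.csv"),
    table = file.path(out_dir, "table.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    forecast_slides = file.path(out_dir, "forecast_slides.csv"),
    forecast_summary = file.path(out_dir, "forecast_summary.csv")
  )
  write.csv(parts$measurements, paths[["measurements"]], row.names = FALSE)
  write.csv(parts$heights, paths[["heights"]], row.names = FALSE)
  write.csv(tab, paths[["table"]], row.names = FALSE)
  write.csv(data.frame(descriptor = rownames(corr), corr),
            paths[["correlations"]], row.names = FALSE)
  write.csv(as.data.frame(cv), paths[["forecast_slides"]], row.names = FALSE)
  write.csv(cv_sum, paths[["forecast_summary"]], row.names = FALSE)

  manifest <- list(
    package = "pigmorph",
    package_version = as.character(utils::packageVersion("pigmorph")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(tools::md5sum(unname(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(table = tab, correlations = corr, forecast = cv,
                 forecast_summary = cv_sum, out_dir = out_dir))
}

#' @export
run_pipeline.pig_study <- function(x, config = pipeline_config(), out_dir) {
  ids <- do.call(rbind, lapply(x$records, function(r) data.frame(
    pig_id = r$pig_id, day = r$day, stringsAsFactors = FALSE
  )))
  height_seeds <- derive_seeds(config$seed, nrow(ids))
  pipeline_core(
    ids,
    measure_fun = function(i) measure_video(x$records[[i]]$video, config),
    height_fun = function(i) video_height(x$records[[i]]$video, config,
                                          seed = height_seeds[i]),
    weights = x$weights, config = config, out_dir = out_dir
  )
}

#' @export
run_pipeline.character <- function(x, config = pipeline_config(), out_dir) {
  ids <- read_dataset(x)
  wpath <- file.path(x, "weights.csv")
  if (!file.exists(wpath))
    stop("weights.csv not found under ", x, call. = FALSE)
  weights <- read.csv(wpath, stringsAsFactors = FALSE)
  height_seeds <- derive_seeds(config$seed, nrow(ids))
  pipeline_core(
    ids,
    measure_fun = function(i) measure_video(ids$dir[i], config),
    height_fun = function(i) {
      if (!ids$has_depth[i]) {
        warning("no depth frames for ", ids$pig_id[i], " day ", ids$day[i],
                "; height skipped", call. = FALSE)
        return(NULL)
      }
      video_height(ids$dir[i], config, seed = height_seeds[i])
    },
    weights = weights, config = config, out_dir = out_dir
  )
}
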