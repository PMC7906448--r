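#' Volume image descriptor
#'
#' The product of body length, width (pixels) and height (meters), in the
#' mixed units the descriptors are measured in (px^2 m). No pixel-to-metric
#' calibration is applied.
#'
#' @param length_px,width_px,height_m Positive descriptor values
#'   (vectorized).
#' @return Numeric vector of volumes.
#' @export
compute_volume <- function(length_px, width_px, height_m) {
  if (any(length_px <= 0) || any(width_px <= 0) || any(height_m <= 0))
    stop("descriptors must be positive", call. = FALSE)
  length_px * width_px * height_m
}

#' Join per-video descriptors with scale weights
#'
#' Inner join on (pig_id, day); unmatched keys on either side are reported
#' as messages and dropped (the forecasting stage needs observed weights).
#' Duplicate keys in either input are an error. The volume descriptor is
#' (re)computed from the joined columns.
#'
#' @param descriptors Data frame with pig_id, day, length_px, width_px,
#'   height_m.
#' @param weights Data frame with pig_id, day, weight_kg.
#' @return A `longitudinal_table` data frame, one row per pig-day.
#' @export
join_records <- function(descriptors, weights) {
  need_d <- c("pig_id", "day", "length_px", "width_px", "height_m")
  need_w <- c("pig_id", "day", "weight_kg")
  stopifnot(all(need_d %in% names(descriptors)), all(need_w %in% names(weights)))
  key_d <- paste(descriptors$pig_id, descriptors$day)
  key_w <- paste(weights$pig_id, weights$day)
  if (anyDuplicated(key_d))
    stop("duplicate (pig_id, day) keys in descriptors", call. = FALSE)
  if (anyDuplicated(key_w))
    stop("duplicate (pig_id, day) keys in weights", call. = FALSE)
  if (any(weights$weight_kg <= 0))
    stop("weights must be positive", call. = FALSE)
  only_d <- sum(!key_d %in% key_w)
  only_w <- sum(!key_w %in% key_d)
  if (only_d > 0)
    message(only_d, " descriptor record(s) had no matching weight; dropped")
  if (only_w > 0)
    message(only_w, " weight record(s) had no matching descriptors; dropped")
  out <- merge(descriptors[need_d], weights[need_w], by = c("pig_id", "day"))
  out <- out[order(out$pig_id, out$day), ]
  out$volume <- compute_volume(out$length_px, out$width_px, out$height_m)
  out <- out[c("pig_id", "day", "length_px", "width_px", "height_m",
               "volume", "weight_kg")]
  rownames(out) <- NULL
  class(out) <- c("longitudinal_table", "data.frame")
  out
}

#' Pairwise Pearson correlations of weight and image descriptors
#'
#' The 5 x 5 correlation matrix over body weight and the four descriptors,
#' pooled across all pig-days.
#'
#' @param table A `longitudinal_table` (needs weight_kg, length_px,
#'   width_px, height_m, volume).
#' @return Symmetric 5 x 5 matrix with unit diagonal, dimnames
#'   weight/length/width/height/volume. Constant columns yield `NA` entries
#'   with a warning.
#' @export
pearson_matrix <- function(table) {
  cols <- c(weight = "weight_kg", length = "length_px", width = "width_px",
            height = "height_m", volume = "volume")
  stopifnot(all(cols %in% names(table)))
  if (nrow(table) < 3)
    stop("need at least 3 rows for correlations", call. = FALSE)
  m <- as.matrix(table[, cols])
  colnames(m) <- names(cols)
  const <- apply(m, 2, function(x) sd(x) == 0)
  if (any(const))
    warning("constant column(s): ", paste(names(cols)[const], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  suppressWarnings(r <- cor(m))
  diag(r) <- 1
  r
}
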