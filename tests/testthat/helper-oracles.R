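# Independent reference implementations used as oracles.

# Brute-force minimum-area rotated rectangle: scan rectangle orientations on
# a 0.1-degree grid (period 90 degrees), project the points, and keep the
# orientation minimizing the extent product. Sides are reported under the
# same pixel-footprint convention as rotated_box() (extent + 1).
oracle_min_rect <- function(pts, step_deg = 0.1) {
  best_area <- Inf
  best <- NULL
  for (ang in seq(0, 90 - step_deg / 2, by = step_deg)) {
    th <- ang * pi / 180
    u <- pts[, 1] * cos(th) + pts[, 2] * sin(th)
    v <- -pts[, 1] * sin(th) + pts[, 2] * cos(th)
    du <- diff(range(u))
    dv <- diff(range(v))
    if (du * dv < best_area) {
      best_area <- du * dv
      best <- c(du, dv) + 1
    }
  }
  sort(best, decreasing = TRUE)  # (length, width)
}

# Agreement between the calipers box and the grid oracle: sides within
# 1 px, or — when two orientations give near-tied minimum areas and the
# grid picks the other one — the calipers area must be at least as small
# (i.e., the exact search never loses to the grid search).
min_rect_agrees <- function(lw_fast, lw_slow) {
  if (max(abs(lw_fast - lw_slow)) < 1) return(TRUE)
  prod(lw_fast - 1) <= prod(lw_slow - 1) + 1e-6
}

# Pixel count of a rasterized rotated ellipse on the integer grid.
oracle_ellipse_area <- function(a, b, cx, cy, theta_deg, width, height) {
  th <- theta_deg * pi / 180
  xs <- rep(0:(width - 1), each = height)
  ys <- rep(0:(height - 1), times = width)
  u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
  v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
  sum((u / a)^2 + (v / b)^2 <= 1)
}

# Points of an axis-aligned rectangle contour (pixel centres), optionally
# rotated about its centre.
rect_contour <- function(w, h, angle_deg = 0, cx = 0, cy = 0) {
  xs <- c(0:(w - 1), rep(w - 1, h), (w - 1):0, rep(0, h))
  ys <- c(rep(0, w), 0:(h - 1), rep(h - 1, w), (h - 1):0)
  xs <- xs - (w - 1) / 2
  ys <- ys - (h - 1) / 2
  th <- angle_deg * pi / 180
  cbind(cx + xs * cos(th) - ys * sin(th), cy + xs * sin(th) + ys * cos(th))
}

# Dense point sample of an ellipse outline.
ellipse_contour <- function(a, b, angle_deg = 0, cx = 0, cy = 0, n = 720) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  th <- angle_deg * pi / 180
  u <- a * cos(t)
  v <- b * sin(t)
  cbind(cx + u * cos(th) - v * sin(th), cy + u * sin(th) + v * cos(th))
}

# A gray frame containing the given foreground rectangles (row/col bounds
# are 1-based inclusive), on a dark floor.
gray_with_blobs <- function(h, w, blobs, fg = 200L, bg = 40L) {
  g <- matrix(bg, h, w)
  for (b in blobs) g[b[1]:b[2], b[3]:b[4]] <- fg
  g
}

# Closed-form population correlation matrix of (weight, L, W, H, volume is
# excluded) under the growth generator, treating day as uniform on
# 0..n_days-1. Used to check pearson_matrix() against simulate_growth().
oracle_growth_cor <- function(g) {
  tt <- seq(0, g$n_days - 1)
  vt <- mean((tt - mean(tt))^2)  # population variance of the day index
  vL <- g$start_L_sd^2 + g$growth_L^2 * vt + g$jitter_L^2
  vW <- g$start_W_sd^2 + g$growth_W^2 * vt + g$jitter_W^2
  vH <- g$start_H_sd^2 + g$growth_H^2 * vt + g$jitter_H^2
  cLW <- g$growth_L * g$growth_W * vt
  cLH <- g$growth_L * g$growth_H * vt
  cWH <- g$growth_W * g$growth_H * vt
  S <- matrix(c(vL, cLW, cLH, cLW, vW, cWH, cLH, cWH, vH), 3, 3)
  b <- c(g$beta_L, g$beta_W, g$beta_H)
  vy <- as.numeric(t(b) %*% S %*% b) + g$sigma_animal^2 + g$sigma_resid^2
  cyx <- as.numeric(S %*% b)
  full <- rbind(c(vy, cyx), cbind(cyx, S))
  stats::cov2cor(full)  # order: weight, length, width, height
}

# ANOVA moment estimator of the between-animal variance for a balanced
# one-way layout (n animals x d days), applied to model residuals.
oracle_anova_sigma2_animal <- function(values, animal) {
  d <- length(values) / length(unique(animal))
  msb <- d * var(tapply(values, animal, mean))
  msw <- mean(tapply(values, animal, var))
  (msb - msw) / d
}
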