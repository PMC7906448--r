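#' Growth-simulation configuration
#'
#' Parameters of the longitudinal generator: each animal carries a normally
#' distributed random intercept, descriptors grow linearly from randomized
#' starting sizes, and daily body weight is a linear function of length,
#' width and height plus the animal effect and residual noise:
#' \deqn{y_{it} = \beta_0 + \beta_L L_{it} + \beta_W W_{it} + \beta_H H_{it}
#'   + a_i + e_{it}, \quad a_i \sim N(0, \sigma_a^2),\;
#'   e_{it} \sim N(0, \sigma_e^2).}
#'
#' Defaults emulate a grower trial: 8 animals followed for 38 days, entering
#' around 23 kg and gaining roughly 0.5 kg/d, with a 6 kg between-animal
#' standard deviation and 1 kg day-to-day measurement noise.
#'
#' @param n_animals,n_days Cohort size and trial length in days
#'   (`n_days >= 15`, one 14-day training window plus a forecast day).
#' @param beta0 Intercept (kg).
#' @param beta_L,beta_W,beta_H Weight per unit descriptor (kg/px, kg/px,
#'   kg/m).
#' @param sigma_animal,sigma_resid Animal-effect and residual standard
#'   deviations (kg).
#' @param growth_L,growth_W,growth_H Mean per-day descriptor increments
#'   (px/d, px/d, m/d).
#' @param jitter_L,jitter_W,jitter_H Day-to-day standard deviations of the
#'   realized descriptors around their growth lines (px, px, m): posture and
#'   gut-fill make daily body measurements fluctuate, and without such
#'   fluctuation the three descriptors would be collinear in time.
#' @param start_L_mean,start_L_sd,start_W_mean,start_W_sd,start_H_mean,start_H_sd
#'   Distribution of day-1 descriptor values across animals.
#' @param rng_seed Integer seed.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(n_animals = 8L, n_days = 38L, beta0 = -6,
                          beta_L = 0.08, beta_W = 0.12, beta_H = 25,
                          sigma_animal = 6, sigma_resid = 1,
                          growth_L = 3, growth_W = 1.3, growth_H = 0.0045,
                          jitter_L = 2, jitter_W = 1, jitter_H = 0.01,
                          start_L_mean = 150, start_L_sd = 12,
                          start_W_mean = 63, start_W_sd = 5,
                          start_H_mean = 0.38, start_H_sd = 0.025,
                          rng_seed = 1L) {
  g <- list(
    n_animals = as.integer(n_animals), n_days = as.integer(n_days),
    beta0 = beta0, beta_L = beta_L, beta_W = beta_W, beta_H = beta_H,
    sigma_animal = sigma_animal, sigma_resid = sigma_resid,
    growth_L = growth_L, growth_W = growth_W, growth_H = growth_H,
    jitter_L = jitter_L, jitter_W = jitter_W, jitter_H = jitter_H,
    start_L_mean = start_L_mean, start_L_sd = start_L_sd,
    start_W_mean = start_W_mean, start_W_sd = start_W_sd,
    start_H_mean = start_H_mean, start_H_sd = start_H_sd,
    rng_seed = as.integer(rng_seed)
  )
  if (g$sigma_animal < 0) stop("sigma_animal must be >= 0", call. = FALSE)
  if (g$sigma_resid <= 0) stop("sigma_resid must be > 0", call. = FALSE)
  if (g$n_days < 15L)
    stop("n_days must be >= 15 (a 14-day window plus one forecast day)",
         call. = FALSE)
  if (g$n_animals < 1L) stop("n_animals must be >= 1", call. = FALSE)
  class(g) <- "growth_config"
  g
}

#' Simulate longitudinal descriptor and weight data
#'
#' Generates one row per animal-day with descriptors (length, width, height,
#' and the derived volume) and a body weight following the random-intercept
#' model described in [growth_config()]. The true parameters used (fixed
#' effects, variance components, realized animal effects) are returned so
#' model-recovery tests can compare estimates against them.
#'
#' @param g A [growth_config()].
#' @param seed Optional seed overriding `g$rng_seed`.
#' @return A list with `table` (a `longitudinal_table` data frame with
#'   columns pig_id, day, length_px, width_px, height_m, volume, weight_kg)
#'   and `params` (beta, sigma_animal, sigma_resid, animal_effects).
#' @export
simulate_growth <- function(g = growth_config(), seed = NULL) {
  stopifnot(inherits(g, "growth_config"))
  old <- local_seed(if (is.null(seed)) g$rng_seed else seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- g$n_animals
  d <- g$n_days
  a_i <- rnorm(n, 0, g$sigma_animal)
  L0 <- rnorm(n, g$start_L_mean, g$start_L_sd)
  W0 <- rnorm(n, g$start_W_mean, g$start_W_sd)
  H0 <- rnorm(n, g$start_H_mean, g$start_H_sd)
  pig_id <- rep(sprintf("pig%02d", seq_len(n)), each = d)
  day <- rep(seq_len(d), times = n)
  tt <- day - 1
  L <- rep(L0, each = d) + g$growth_L * tt + rnorm(n * d, 0, g$jitter_L)
  W <- rep(W0, each = d) + g$growth_W * tt + rnorm(n * d, 0, g$jitter_W)
  H <- rep(H0, each = d) + g$growth_H * tt + rnorm(n * d, 0, g$jitter_H)
  e <- rnorm(n * d, 0, g$sigma_resid)
  y <- g$beta0 + g$beta_L * L + g$beta_W * W + g$beta_H * H +
    rep(a_i, each = d) + e
  tab <- data.frame(
    pig_id = pig_id, day = day, length_px = L, width_px = W, height_m = H,
    volume = L * W * H, weight_kg = y, stringsAsFactors = FALSE
  )
  class(tab) <- c("longitudinal_table", "data.frame")
  list(
    table = tab,
    params = list(
      beta = c(intercept = g$beta0, length_px = g$beta_L,
               width_px = g$beta_W, height_m = g$beta_H),
      sigma_animal = g$sigma_animal, sigma_resid = g$sigma_resid,
      animal_effects = setNames(a_i, sprintf("pig%02d", seq_len(n)))
    )
  )
}
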