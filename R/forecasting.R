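#' Fit the random-intercept weight model
#'
#' REML fit of `weight_kg ~ length_px + width_px + height_m + (1 | pig_id)`:
#' fixed morphological descriptors plus a normally distributed per-animal
#' intercept. Volume is never included as a fixed effect, to avoid the
#' multicollinearity of a descriptor that is the product of the other three.
#' Animal effects are the conditional modes (BLUPs) from the fit.
#'
#' @param train A `longitudinal_table` with at least 2 animals.
#' @return An object of class `lmm_fit`: list with `beta` (intercept and
#'   three slopes), `sigma2_animal`, `sigma2_resid`, `animal_effects`
#'   (named kg vector, one per training animal), `training_keys`, and the
#'   underlying `lme4` model in `model`.
#' @export
fit_random_intercept <- function(train) {
  stopifnot(all(c("pig_id", "day", "length_px", "width_px", "height_m",
                  "weight_kg") %in% names(train)))
  if (length(unique(train$pig_id)) < 2)
    stop("need at least 2 animals to separate animal and residual variance",
         call. = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(weight_kg ~ length_px + width_px + height_m + (1 | pig_id),
               data = train, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2a <- vc$vcov[vc$grp == "pig_id"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  re <- lme4::ranef(fit)$pig_id
  structure(
    list(
      beta = setNames(lme4::fixef(fit),
                      c("intercept", "length_px", "width_px", "height_m")),
      sigma2_animal = s2a, sigma2_resid = s2e,
      animal_effects = setNames(re[, 1], rownames(re)),
      training_keys = paste(train$pig_id, train$day),
      model = fit
    ),
    class = "lmm_fit"
  )
}

#' Predict body weight from a fitted random-intercept model
#'
#' `LMM1` uses the fixed descriptors alone (population prediction, animal
#' effect set to zero); `LMM2` adds the training-window BLUP of each
#' animal's intercept. An animal absent from training falls back to a zero
#' effect under LMM2, with a warning.
#'
#' @param object An `lmm_fit`.
#' @param newdata Data frame of test rows (pig_id, length_px, width_px,
#'   height_m).
#' @param mode `"LMM1"` or `"LMM2"`.
#' @param ... Unused.
#' @return Numeric vector of predicted weights (kg).
#' @export
predict.lmm_fit <- function(object, newdata, mode = c("LMM2", "LMM1"), ...) {
  mode <- match.arg(mode)
  if (any(is.na(newdata$length_px) | is.na(newdata$width_px) |
          is.na(newdata$height_m)))
    stop("missing descriptor values in test rows", call. = FALSE)
  b <- object$beta
  yhat <- b[["intercept"]] + b[["length_px"]] * newdata$length_px +
    b[["width_px"]] * newdata$width_px + b[["height_m"]] * newdata$height_m
  if (mode == "LMM2") {
    a <- object$animal_effects[as.character(newdata$pig_id)]
    if (anyNA(a)) {
      warning("animal(s) not in training set; using zero animal effect",
              call. = FALSE)
      a[is.na(a)] <- 0
    }
    yhat <- yhat + unname(a)
  }
  unname(yhat)
}

#' Sliding-window cross-validation scenarios
#'
#' For each forecast horizon, enumerates every training-window start `s`
#' such that calendar days `s .. s + window_days - 1` and the test day
#' `s + window_days - 1 + horizon` are all present in the data.
#'
#' @param days Sorted vector of distinct observation days.
#' @param window_days Training-window length in days (default 14).
#' @param horizons Forecast horizons in days.
#' @return List of scenarios, each with `window_days`, `horizon` and
#'   `slide_starts`.
#' @export
make_scenarios <- function(days, window_days = 14, horizons = 1:4) {
  days <- sort(unique(days))
  scen <- lapply(horizons, function(h) {
    starts <- Filter(function(s) {
      all(s:(s + window_days - 1) %in% days) &&
        (s + window_days - 1 + h) %in% days
    }, days)
    list(window_days = window_days, horizon = h,
         slide_starts = as.numeric(starts))
  })
  if (all(vapply(scen, function(s) length(s$slide_starts), 1L) == 0))
    stop("no feasible slide for any horizon: too few days", call. = FALSE)
  scen
}

#' Prediction coefficient of determination
#'
#' By default the squared Pearson correlation between observed and
#' predicted values, which lies in `[0, 1]`; `method = "ssr"` gives the
#' alternative `1 - SSE/SST`, which can be negative for poor forecasts.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @param method `"cor"` (squared correlation) or `"ssr"` (1 - SSE/SST).
#' @return Numeric scalar.
#' @export
prediction_r2 <- function(observed, predicted, method = c("cor", "ssr")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (sd(observed) == 0)
    stop("observed values are constant; R2 undefined", call. = FALSE)
  if (method == "cor") {
    if (sd(predicted) == 0)
      stop("predicted values are constant; R2 undefined", call. = FALSE)
    cor(observed, predicted)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' Mean absolute error
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return MAE in the units of the inputs (kg for weights).
#' @export
mae <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  mean(abs(observed - predicted))
}

#' Move-forward time-series cross-validation of weight forecasting
#'
#' For every horizon and window start, fits the random-intercept model on
#' the 14-day (by default) training window and forecasts the test day for
#' every animal observed on it, under both prediction modes: descriptors
#' alone (LMM1) and descriptors plus animal effect (LMM2). Each slide
#' contributes one prediction R-squared and MAE computed across animals at
#' the forecast day. A window start shared by several horizons is fitted
#' once. Slides whose fit fails are skipped with a warning.
#'
#' @param table A `longitudinal_table`.
#' @param window_days Training-window length (days).
#' @param horizons Forecast horizons (days ahead).
#' @param modes Prediction modes to evaluate.
#' @param r2_method Passed to [prediction_r2()].
#' @return A data frame of class `forecast_cv`, one row per
#'   (model, horizon, start): columns `model`, `horizon`, `start_day`,
#'   `test_day`, `n_test`, `r2`, `mae_kg`.
#' @export
run_cv <- function(table, window_days = 14, horizons = 1:4,
                   modes = c("LMM1", "LMM2"), r2_method = c("cor", "ssr")) {
  r2_method <- match.arg(r2_method)
  stopifnot(inherits(table, "data.frame"))
  scen <- make_scenarios(unique(table$day), window_days, horizons)
  starts <- sort(unique(unlist(lapply(scen, `[[`, "slide_starts"))))
  fits <- new.env(parent = emptyenv())
  get_fit <- function(s) {
    key <- as.character(s)
    if (is.null(fits[[key]])) {
      train <- table[table$day >= s & table$day <= s + window_days - 1, ,
                     drop = FALSE]
      fits[[key]] <- tryCatch(fit_random_intercept(train),
                              error = function(e) e)
    }
    fits[[key]]
  }
  rows <- list()
  for (sc in scen) {
    for (s in sc$slide_starts) {
      fit <- get_fit(s)
      if (inherits(fit, "error")) {
        warning(sprintf("slide at day %s skipped: %s", s, fit$message),
                call. = FALSE)
        next
      }
      test_day <- s + window_days - 1 + sc$horizon
      test <- table[table$day == test_day & !is.na(table$weight_kg), ,
                    drop = FALSE]
      if (nrow(test) < 2) next
      for (mode in modes) {
        pred <- predict(fit, test, mode = mode)
        rows[[length(rows) + 1]] <- data.frame(
          model = mode, horizon = sc$horizon, start_day = s,
          test_day = test_day, n_test = nrow(test),
          r2 = prediction_r2(test$weight_kg, pred, r2_method),
          mae_kg = mae(test$weight_kg, pred), stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("forecast_cv", "data.frame")
  out
}

#' Summarize cross-validation results per model and horizon
#'
#' @param object A `forecast_cv` data frame from [run_cv()].
#' @param ... Unused.
#' @return Data frame with one row per (model, horizon): number of slides
#'   and min / median / max prediction R-squared plus median MAE.
#' @method summary forecast_cv
#' @export
summary.forecast_cv <- function(object, ...) {
  sp <- split(object, list(object$model, object$horizon), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    model = d$model[1], horizon = d$horizon[1], n_slides = nrow(d),
    r2_min = min(d$r2), r2_median = median(d$r2), r2_max = max(d$r2),
    mae_median_kg = median(d$mae_kg), stringsAsFactors = FALSE
  )))
  out <- out[order(out$model, out$horizon), ]
  rownames(out) <- NULL
  out
}
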