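make_fit <- function(beta, effects) {
  structure(list(beta = setNames(beta, c("intercept", "length_px",
                                         "width_px", "height_m")),
                 sigma2_animal = 1, sigma2_resid = 1,
                 animal_effects = effects, training_keys = character()),
            class = "lmm_fit")
}

test_that("random-intercept fit recovers known parameters", {
  g <- growth_config(n_animals = 100, n_days = 20, rng_seed = 3)
  sim <- simulate_growth(g)
  fit <- fit_random_intercept(sim$table)
  se <- sqrt(diag(as.matrix(vcov(fit$model))))
  truth <- c(-6, 0.08, 0.12, 25)
  expect_true(all(abs(fit$beta - truth) <= 3 * se))
  expect_lt(abs(fit$sigma2_animal - 36) / 36, 0.40)
  expect_lt(abs(fit$sigma2_resid - 1), 0.25)
  expect_equal(sort(names(fit$animal_effects)),
               sort(unique(sim$table$pig_id)))

  # boundary case: no animal variance
  g0 <- growth_config(n_animals = 30, n_days = 15, sigma_animal = 0,
                      rng_seed = 4)
  fit0 <- fit_random_intercept(simulate_growth(g0)$table)
  expect_lt(fit0$sigma2_animal, 0.5)

  expect_error(fit_random_intercept(
    simulate_growth(growth_config(n_animals = 1, n_days = 16))$table
  ), "2 animals")
})

test_that("animal-variance estimate matches the ANOVA moment oracle", {
  # balanced layout; residualize on the true fixed effects so the one-way
  # ANOVA estimator targets the same decomposition as REML
  g <- growth_config(n_animals = 40, n_days = 15, sigma_animal = 5,
                     sigma_resid = 1, rng_seed = 8)
  sim <- simulate_growth(g)
  fit <- fit_random_intercept(sim$table)
  resid <- with(sim$table, weight_kg - (g$beta0 + g$beta_L * length_px +
    g$beta_W * width_px + g$beta_H * height_m))
  s2a_anova <- oracle_anova_sigma2_animal(resid, sim$table$pig_id)
  expect_lt(abs(fit$sigma2_animal - s2a_anova) / s2a_anova, 0.10)
})

test_that("LMM1 and LMM2 predictions differ exactly by the animal effect", {
  fit <- make_fit(c(0, 1, 0, 0), c(P = 2))
  row <- data.frame(pig_id = "P", length_px = 100, width_px = 7,
                    height_m = 0.1)
  expect_equal(predict(fit, row, mode = "LMM1"), 100)
  expect_equal(predict(fit, row, mode = "LMM2"), 102)

  # all-zero effects: the two modes coincide
  fit0 <- make_fit(c(1, 0.1, 0.2, 10), c(A = 0, B = 0))
  rows <- data.frame(pig_id = c("A", "B"), length_px = c(100, 120),
                     width_px = c(40, 50), height_m = c(0.4, 0.5))
  expect_equal(predict(fit0, rows, "LMM1"), predict(fit0, rows, "LMM2"))

  # unseen animal falls back to zero effect with a warning
  expect_warning(p <- predict(fit, data.frame(pig_id = "Q", length_px = 50,
                                              width_px = 1, height_m = 1),
                              mode = "LMM2"), "not in training")
  expect_equal(p, 50)
  expect_error(predict(fit, data.frame(pig_id = "P", length_px = NA,
                                       width_px = 1, height_m = 1)),
               "missing descriptor")
})

test_that("strong animal effects make LMM2 beat LMM1 in MAE", {
  deltas <- sapply(1:20, function(s) {
    g <- growth_config(sigma_animal = 8, sigma_resid = 0.5,
                       rng_seed = 300 + s)
    tab <- simulate_growth(g)$table
    train <- tab[tab$day <= 14, ]
    test <- tab[tab$day == 15, ]
    fit <- fit_random_intercept(train)
    mae(test$weight_kg, predict(fit, test, "LMM1")) -
      mae(test$weight_kg, predict(fit, test, "LMM2"))
  })
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.9)
})

test_that("scenario enumeration counts the feasible slides", {
  s1 <- make_scenarios(1:38, 14, 1)
  expect_equal(length(s1[[1]]$slide_starts), 24)
  expect_equal(range(s1[[1]]$slide_starts), c(1, 24))
  s4 <- make_scenarios(1:38, 14, 4)
  expect_equal(length(s4[[1]]$slide_starts), 21)
  expect_error(make_scenarios(1:15, 14, 4), "too few days")
  # a missing calendar day removes the windows that need it
  s_gap <- make_scenarios(setdiff(1:38, 20), 14, 1)
  expect_true(all(vapply(s_gap[[1]]$slide_starts, function(s)
    !(20 %in% c(s:(s + 13), s + 14)), TRUE)))
})

test_that("prediction R2 and MAE follow their definitions", {
  expect_equal(prediction_r2(1:10, 1:10), 1)
  expect_equal(prediction_r2(1:10, 3 + 2 * (1:10)), 1)  # affine invariance
  obs <- c(1, 2, 3, 4)
  pred <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(prediction_r2(obs, pred), cor(obs, pred)^2)
  expect_equal(prediction_r2(obs, pred, "ssr"),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
  expect_error(prediction_r2(rep(1, 4), 1:4), "constant")

  expect_equal(mae(c(10, 20), c(10, 20)), 0)
  expect_equal(mae(c(10, 20), c(12, 18)), 2)
  expect_equal(mae(1:3, rep(2, 3)), 2 / 3)
})

test_that("run_cv produces the expected slides and perfect noise-free fits", {
  g <- growth_config(sigma_animal = 0, sigma_resid = 1e-8, rng_seed = 5)
  tab <- simulate_growth(g)$table
  cv <- run_cv(tab)
  counts <- table(cv$model, cv$horizon)
  expect_equal(unname(counts["LMM1", ]), c(24, 23, 22, 21))
  expect_equal(unname(counts["LMM2", ]), c(24, 23, 22, 21))
  expect_true(all(cv$r2 > 1 - 1e-6))
  expect_true(all(cv$mae_kg < 1e-3))
  expect_true(all(cv$n_test == 8))
})

test_that("LMM1 is label-permutation invariant; LMM2 is not", {
  g <- growth_config(sigma_animal = 6, rng_seed = 17)
  tab <- simulate_growth(g)$table
  train <- tab[tab$day <= 14, ]
  test <- tab[tab$day == 15, ]
  fit <- fit_random_intercept(train)
  perm <- test
  perm$pig_id <- rev(perm$pig_id)
  expect_equal(predict(fit, perm, "LMM1"), predict(fit, test, "LMM1"))
  expect_false(isTRUE(all.equal(predict(fit, perm, "LMM2"),
                                predict(fit, test, "LMM2"))))
})

test_that("a drifting weight-descriptor relationship degrades with horizon", {
  med_by_h <- sapply(1:8, function(s) {
    g <- growth_config(sigma_animal = 2, sigma_resid = 0.6,
                       rng_seed = 400 + s)
    tab <- simulate_growth(g)$table
    # the length coefficient drifts upward over the trial
    tab$weight_kg <- tab$weight_kg + 0.012 * (tab$day - 1) * tab$length_px
    cv <- run_cv(tab, modes = "LMM2")
    tapply(cv$r2, cv$horizon, median)
  })
  avg <- rowMeans(med_by_h)
  expect_true(all(diff(avg) <= 0.01))  # non-increasing up to noise
})
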