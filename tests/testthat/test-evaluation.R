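test_that("squared-correlation R2 behaves like a correlation", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, 2 * obs + 5), 1)  # affine invariance
  # independent two-pass arithmetic: centered cross-moment 3, sums of
  # squares 2 and 14/3, so R2 = 3^2 / (2 * 14/3) = 27/28
  expect_equal(r_squared(obs, c(1, 2, 4)), 27 / 28)
  expect_error(r_squared(obs, c(2, 2, 2)), "zero variance")
  # the coefficient of determination is a different statistic
  expect_lt(coefficient_of_determination(obs, 2 * obs + 5), 1)
})

test_that("error metrics match hand arithmetic", {
  obs <- c(1e-4, 2e-4)
  est <- c(1.1e-4, 1.8e-4)
  expect_equal(mae(obs, est), 1.5e-5)
  expect_equal(mape(obs, est), 0.10)
  expect_equal(aard_percent(obs, est), 10)
  expect_equal(mae(obs, obs), 0)
  expect_equal(mape(obs, obs), 0)
  expect_error(mape(c(0, 1), c(1, 1)), "position 1")
})

test_that("evaluate_model reports over the prediction/observation pairing", {
  ds <- decitabine_dataset()
  full_tree <- fit_tree(ds)
  rep <- evaluate_model(full_tree, ds)
  expect_equal(rep$r2, 1)
  expect_equal(rep$mae, 0)
  expect_equal(rep$n, 32L)
  # a constant predictor has no defined squared correlation
  stump <- fit_tree(ds, tree_config(max_depth = 0))
  expect_error(evaluate_model(stump, ds), "zero variance")
})

test_that("grid search is exhaustive, consistent, and covers >1000 combinations", {
  for (fam in c("gpr", "krr", "tree")) {
    g <- default_grid(fam)
    expect_gt(nrow(expand.grid(g)), 1000)
  }

  ds <- decitabine_dataset()
  single <- grid_search(ds, "krr",
                        grid = list(lambda = 1e-8, length_scale = 0.7))
  expect_equal(single$best$lambda, 1e-8)
  expect_equal(nrow(single$results), 1L)

  gs <- grid_search(ds, "tree",
                    grid = list(max_depth = 1:5, min_samples_leaf = 1:3,
                                min_samples_split = 2L),
                    metric = "mape")
  expect_equal(nrow(gs$results), 15L)
  expect_equal(gs$best_score, min(gs$results$score, na.rm = TRUE))
  # brute-force re-scan of the returned table reproduces the winner
  i <- which.min(gs$results$score)
  expect_equal(gs$results$max_depth[i], gs$best$max_depth)

  gs2 <- grid_search(ds, "tree",
                     grid = list(max_depth = 1:5, min_samples_leaf = 1:3,
                                 min_samples_split = 2L),
                     split = "holdout", seed = 5)
  gs3 <- grid_search(ds, "tree",
                     grid = list(max_depth = 1:5, min_samples_leaf = 1:3,
                                 min_samples_split = 2L),
                     split = "holdout", seed = 5)
  expect_identical(gs2$results$score, gs3$results$score)
})

test_that("response surfaces are row-major grids consistent with prediction", {
  ds <- decitabine_dataset()
  fit <- gpr_fit(ds, seed = 1)
  one <- predict_surface(fit, 250, 320)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean,
               predict(fit, data.frame(pressure_bar = 250,
                                       temperature_K = 320))$mean)

  surf <- predict_surface(fit, unique(ds$pressure_bar),
                          unique(ds$temperature_K))
  expect_equal(nrow(surf), 32L)
  # temperature varies fastest
  expect_equal(surf$temperature_K[1:4], seq(308, 338, by = 10))
  merged <- merge(as.data.frame(ds), surf)
  expect_equal(merged$mean, merged$solubility_molefrac, tolerance = 0.02)

  # CSV export round trip
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(surf, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$mean, surf$mean, tolerance = 1e-12)
})

test_that("the optimum search finds interior grid maxima and domain corners", {
  # monotone toy surface y = P*T peaks at the domain corner
  toy <- structure(list(), class = "toy_model")
  predict_solubility.toy_model <- function(model, pressure, temperature)
    pressure * temperature
  registerS3method("predict_solubility", "toy_model",
                   predict_solubility.toy_model)
  opt <- find_optimum(toy, c(120, 400), c(308, 338), resolution = 5)
  expect_equal(opt$pressure_bar, 400)
  expect_equal(opt$temperature_K, 338)

  ds <- decitabine_dataset()
  fit <- gpr_fit(ds, seed = 1)
  opt <- find_optimum(fit)
  expect_equal(opt$pressure_bar, 400, tolerance = 1e-6)
  expect_equal(opt$temperature_K, 338, tolerance = 1e-6)
  expect_equal(opt$solubility, 1.07e-3, tolerance = 0.02)
})

test_that("crossover location matches the isotherm geometry", {
  ds <- decitabine_dataset()
  cr <- crossover_pressure(ds, 308, 338)
  expect_equal(cr$bracket, c(160, 200))
  # the measured deltas flip sign across the bracket
  expect_lt(7.79e-5 - 8.23e-5, 0)
  expect_gt(2.05e-4 - 1.18e-4, 0)

  fit <- gpr_fit(ds, seed = 1)
  crm <- crossover_pressure(fit, 308, 338)
  expect_false(is.na(crm$crossover_pressure))
  expect_gte(crm$crossover_pressure, crm$bracket[1])
  expect_lte(crm$crossover_pressure, crm$bracket[2])
  # re-evaluating the model across the reported crossover flips the sign
  lo <- predict_solubility(fit, crm$crossover_pressure - 5, 338) -
    predict_solubility(fit, crm$crossover_pressure - 5, 308)
  hi <- predict_solubility(fit, crm$crossover_pressure + 5, 338) -
    predict_solubility(fit, crm$crossover_pressure + 5, 308)
  expect_lt(lo, 0)
  expect_gt(hi, 0)

  # strictly parallel isotherms never cross
  gen <- generate_solubility(synthetic_config("bartle", c(-11, 0, 0.004),
                                              noise_sd = 0, seed = 1))
  parallel_fit <- fit_correlation(gen$dataset, "bartle", n_starts = 2,
                                  seed = 1)
  none <- crossover_pressure(parallel_fit, 308, 338)
  expect_true(is.na(none$crossover_pressure))
  expect_null(none$bracket)
})
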