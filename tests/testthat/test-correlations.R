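test_that("correlation forms evaluate their defining equations", {
  # constant limit: with a1 = a2 = 0 the K-J form is e^a0 everywhere
  expect_equal(evaluate_correlation("kumar_johnston", c(-8, 0, 0),
                                    c(308, 338), c(120, 400), c(700, 900)),
               rep(exp(-8), 2))
  # Bartle with a2 = 0 is density-independent: ln(y P) = a0 + a1/T
  y1 <- evaluate_correlation("bartle", c(20, -9000, 0), 318, 200, 600)
  y2 <- evaluate_correlation("bartle", c(20, -9000, 0), 318, 200, 900)
  expect_equal(y1, y2)
  expect_equal(log(y1 * 200), 20 - 9000 / 318)
  # and is monotone in 1/T
  ys <- evaluate_correlation("bartle", c(20, -9000, 0),
                             c(308, 318, 328), 200, 700)
  expect_true(all(diff(ys) > 0))

  expect_error(evaluate_correlation("kumar_johnston", c(1, 2), 318, 200, 700),
               "3 parameters")
  expect_error(evaluate_correlation("kumar_johnston", c(1, 2, 3), 318, 200, -1),
               "density")
  expect_error(evaluate_correlation("nope", c(1), 318, 200, 700), "unknown")
})

test_that("published K-J parameters reproduce the measured solubility scale", {
  rho <- co2_density(338, 400)$density_kg_m3
  y <- evaluate_correlation("kumar_johnston", c(7.32, -7108.7, 0.00769),
                            338, 400, rho)
  expect_gt(y, 1.07e-3 / 1.3)
  expect_lt(y, 1.07e-3 * 1.3)
})

test_that("noiseless parameter recovery is exact to optimizer tolerance", {
  for (form in c("kumar_johnston", "bartle")) {
    truth <- if (form == "kumar_johnston") c(7.32, -7108.7, 0.00769)
             else c(25.15, -9537.9, 0.0122)
    gen <- generate_solubility(synthetic_config(form, truth, noise_sd = 0,
                                                seed = 11))
    fit <- fit_correlation(gen$dataset, form, n_starts = 4, seed = 2)
    expect_lt(max(abs((fit$params - truth) / truth)), 1e-3)
    expect_lt(fit$aard, 1e-6)
  }
})

test_that("noiseless recovery holds across random ground truths", {
  set.seed(99)
  for (i in 1:10) {
    truth <- c(runif(1, 5, 9), runif(1, -9000, -6000), runif(1, 0.004, 0.01))
    gen <- generate_solubility(synthetic_config("kumar_johnston", truth,
                                                noise_sd = 0, seed = 50 + i))
    fit <- fit_correlation(gen$dataset, "kumar_johnston", n_starts = 4,
                           seed = i)
    expect_lt(max(abs((fit$params - truth) / truth)), 1e-3)
  }
})

test_that("AARD is scale invariant and the fit never worsens the initial guess", {
  obs <- c(1e-4, 2e-4, 3e-4)
  est <- c(1.2e-4, 1.9e-4, 3.3e-4)
  expect_equal(aard_percent(obs, est), aard_percent(obs * 50, est * 50))

  ds <- decitabine_dataset()
  rho <- density_grid(ds)$density_kg_m3
  init <- unname(coef(lm(log(ds$solubility_molefrac) ~
                           I(1 / ds$temperature_K) + rho)))
  init_aard <- aard_percent(ds$solubility_molefrac,
                            evaluate_correlation("kumar_johnston", init,
                                                 ds$temperature_K,
                                                 ds$pressure_bar, rho))
  fit <- fit_correlation(ds, "kumar_johnston", seed = 1)
  expect_lte(fit$aard, init_aard)
})

test_that("user-registered forms plug into fitting", {
  # a Chrastil-like toy form registered at run time
  register_correlation_form("toy_powerlaw", 2L,
    function(params, temperature, pressure, density)
      exp(params[1L]) * density^params[2L],
    overwrite = TRUE)
  ds <- decitabine_dataset()
  fit <- fit_correlation(ds, "toy_powerlaw", n_starts = 6, seed = 3)
  expect_equal(fit$form, "toy_powerlaw")
  expect_true(is.finite(fit$aard))
  expect_true("toy_powerlaw" %in% correlation_form_ids())
})

test_that("correlation report ranks models by AARD with stable ties", {
  ds <- decitabine_dataset()
  kj <- fit_correlation(ds, "kumar_johnston", seed = 1)
  bt <- fit_correlation(ds, "bartle", seed = 1)
  rep2 <- correlation_report(list(kj, bt))
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$form, rep2$form[order(rep2$aard_percent)])
  expect_true(all(is.na(rep2[, c("a3", "a4", "a5")])))

  one <- correlation_report(kj)
  expect_equal(nrow(one), 1L)

  tie <- kj
  tie$form <- "aaa_clone"
  tied <- correlation_report(list(kj, tie))
  expect_equal(tied$form, c("aaa_clone", "kumar_johnston"))
})
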