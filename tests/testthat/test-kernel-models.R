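test_that("squared-exponential kernel has the closed-form values", {
  p4 <- se_kernel_params(signal_variance = 4, length_scale = 1)
  expect_equal(se_kernel(c(0.3, -1.2), c(0.3, -1.2), p4), 4)
  p1 <- se_kernel_params(1, 1)
  expect_equal(se_kernel(c(0, 0), c(1, 0), p1), exp(-0.5))
  expect_equal(se_kernel(c(1, 0), c(0, 0), p1), se_kernel(c(0, 0), c(1, 0), p1))
  # anisotropic scaling: distance along each axis divided by its own scale
  pa <- se_kernel_params(2, c(2, 0.5))
  expect_equal(se_kernel(c(0, 0), c(2, 1), pa),
               2 * exp(-0.5 * ((2 / 2)^2 + (1 / 0.5)^2)))
  expect_error(se_kernel_params(-1, 1), "signal_variance")
  expect_error(se_kernel_params(1, c(1, 0)), "length_scale")
})

test_that("Gram matrices are positive semidefinite for random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(2 * 12), ncol = 2)
    params <- se_kernel_params(exp(runif(1, -1, 2)), exp(runif(2, -1, 1)))
    K <- se_kernel(X, X, params)
    expect_true(isSymmetric(K, tol = 1e-12))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10 * params$signal_variance)
  }
})

test_that("noise-free GPR interpolates its training data", {
  ds <- decitabine_dataset()
  fit <- gpr_fit(ds, seed = 1)
  pred <- predict(fit, as.data.frame(ds))
  expect_equal(pred$mean, ds$solubility_molefrac, tolerance = 1e-6)
  # predictive variance collapses at the training points
  expect_true(all(pred$variance <= 1e-10 * fit$kernel$signal_variance))
})

test_that("GPR fit is deterministic for a fixed seed", {
  ds <- decitabine_dataset()
  f1 <- gpr_fit(ds, seed = 7)
  f2 <- gpr_fit(ds, seed = 7)
  expect_identical(f1$kernel$signal_variance, f2$kernel$signal_variance)
  expect_identical(f1$kernel$length_scale, f2$kernel$length_scale)
})

test_that("log marginal likelihood agrees with the direct dense formula", {
  ds <- random_dataset(6, seed = 3)
  fit <- gpr_fit(ds, noise_variance = 1e-9, n_restarts = 2, seed = 1)
  K <- se_kernel(fit$X, fit$X, fit$kernel) +
    diag(fit$noise_variance + fit$jitter, nrow(fit$X))
  direct <- -0.5 * drop(fit$y %*% solve(K, fit$y)) -
    0.5 * determinant(K)$modulus[1] - 0.5 * length(fit$y) * log(2 * pi)
  expect_equal(log_marginal_likelihood(fit), direct, tolerance = 1e-8)
})

test_that("GPR posterior matches hand-computed conditioning on two points", {
  ds <- solubility_dataset(c(100, 300), c(310, 310), c(1e-4, 5e-4))
  fit <- gpr_fit(ds, kernel0 = se_kernel_params(1e-7, 1), strategy = "grid",
                 grid = list(signal_variance = 1e-7, length_scale_P = 1,
                             length_scale_T = 1))
  K <- se_kernel(fit$X, fit$X, fit$kernel) + diag(fit$jitter, 2)
  xs <- c(200, 310)
  Xs <- sweep(sweep(matrix(xs, 1), 2, fit$x_center), 2, fit$x_scale, "/")
  ks <- se_kernel(Xs, fit$X, fit$kernel)
  pred <- predict(fit, data.frame(pressure_bar = 200, temperature_K = 310))
  expect_equal(pred$mean, drop(ks %*% solve(K, fit$y)), tolerance = 1e-10)
  expect_equal(pred$variance,
               drop(fit$kernel$signal_variance - ks %*% solve(K, t(ks))),
               tolerance = 1e-12)
})

test_that("predictive variance grows with distance from the training set", {
  ds <- decitabine_dataset()
  fit <- gpr_fit(ds, seed = 1)
  # walk away from the data along a pressure ray at fixed T
  ps <- c(400, 450, 500, 600, 800)
  v <- predict(fit, data.frame(pressure_bar = ps, temperature_K = 323))$variance
  expect_true(all(diff(v) > 0))
})

test_that("KRR single-point fit matches the scalar closed form", {
  ds <- solubility_dataset(200, 318, 1.55e-4)
  kern <- se_kernel_params(2, 1)
  lambda <- 0.3
  fit <- krr_fit(ds, kern, lambda)
  # N = 1: f(x1) = k11 / (k11 + lambda) * y1, with k11 = signal variance
  expect_equal(predict(fit, as.data.frame(ds)),
               2 / (2 + lambda) * 1.55e-4, tolerance = 1e-12)
})

test_that("KRR approaches interpolation as regularization vanishes", {
  ds <- decitabine_dataset()
  fit <- krr_fit(ds, se_kernel_params(1, 1), lambda = 1e-12)
  pred <- predict(fit, as.data.frame(ds))
  expect_equal(pred, ds$solubility_molefrac, tolerance = 1e-4)
  # kernel bound: |f(x)| <= ||alpha||_1 * sigma_f^2 anywhere
  far <- predict(fit, data.frame(pressure_bar = 900, temperature_K = 400))
  expect_lte(abs(far), sum(abs(fit$alpha)) * fit$kernel$signal_variance)
  expect_error(krr_fit(ds, se_kernel_params(1, 1), lambda = 0), "lambda")
})

test_that("KRR and GPR means coincide when N*lambda equals the noise variance", {
  for (seed in 1:50) {
    n <- sample(3:8, 1)
    ds <- random_dataset(n, seed = 1000 + seed)
    kern <- se_kernel_params(exp(runif(1, -2, 1)), exp(runif(2, -0.7, 0.7)))
    sigma_n2 <- exp(runif(1, log(1e-8), log(1e-3)))
    gpr <- gpr_fit(ds, kernel0 = kern, noise_variance = sigma_n2,
                   strategy = "grid",
                   grid = list(signal_variance = kern$signal_variance,
                               length_scale_P = kern$length_scale[1],
                               length_scale_T = kern$length_scale[2]))
    krr <- krr_fit(ds, kern, lambda = sigma_n2 / n)
    xs <- data.frame(pressure_bar = runif(3, 80, 500),
                     temperature_K = runif(3, 305, 345))
    m_gpr <- predict(gpr, xs)$mean
    m_krr <- predict(krr, xs)
    expect_equal(m_krr, m_gpr, tolerance = 1e-8)
  }
})

test_that("kernel models survive a JSON round trip", {
  ds <- decitabine_dataset()
  path <- withr::local_tempfile(fileext = ".json")
  gpr <- gpr_fit(ds, seed = 1)
  write_model_json(gpr, path)
  gpr2 <- read_model_json(path)
  nd <- data.frame(pressure_bar = c(150, 390), temperature_K = c(312, 336))
  expect_equal(predict(gpr2, nd)$mean, predict(gpr, nd)$mean,
               tolerance = 1e-12)
  krr <- krr_fit(ds, se_kernel_params(1, c(1, 2)), lambda = 1e-6)
  write_model_json(krr, path)
  expect_equal(predict(read_model_json(path), nd), predict(krr, nd),
               tolerance = 1e-12)
})
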