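#' Squared-exponential kernel parameters
#'
#' The squared-exponential (RBF) covariance
#' k(x, x') = sigma_f^2 exp(-sum_d (x_d - x'_d)^2 / (2 l_d^2)).
#' `signal_variance` (sigma_f^2) is the maximum attainable covariance;
#' each `length_scale` l_d controls how quickly correlation decays along
#' input dimension d. A single length scale gives the isotropic kernel.
#'
#' @param signal_variance positive scalar, sigma_f^2.
#' @param length_scale positive scalar or vector (one entry per input
#'   dimension).
#' @return An object of class `se_kernel_params`.
#' @export
se_kernel_params <- function(signal_variance = 1, length_scale = 1) {
  if (!is.numeric(signal_variance) || length(signal_variance) != 1L ||
      !is.finite(signal_variance) || signal_variance <= 0)
    stop("signal_variance must be a positive number", call. = FALSE)
  if (!is.numeric(length_scale) || any(!is.finite(length_scale)) ||
      any(length_scale <= 0))
    stop("length_scale entries must be positive numbers", call. = FALSE)
  structure(list(signal_variance = signal_variance,
                 length_scale = as.numeric(length_scale)),
            class = "se_kernel_params")
}

#' Evaluate the squared-exponential kernel
#'
#' Computes the Gram (cross-covariance) matrix between two sets of input
#' points. Scalars and vectors are treated as single points.
#'
#' @param x,y numeric matrices (rows are points) or vectors (one point).
#'   `y` defaults to `x`.
#' @param params an [se_kernel_params()].
#' @return The `nrow(x)` by `nrow(y)` covariance matrix; a 1x1 matrix
#'   drops to a scalar.
#' @examples
#' se_kernel(c(0, 0), c(1, 0), se_kernel_params(1, 1))  # exp(-1/2)
#' @export
se_kernel <- function(x, y = x, params = se_kernel_params()) {
  stopifnot(inherits(params, "se_kernel_params"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  stopifnot(ncol(x) == ncol(y))
  l <- rep_len(params$length_scale, ncol(x))
  xs <- sweep(x, 2L, l, "/")
  ys <- sweep(y, 2L, l, "/")
  d2 <- outer(rowSums(xs^2), rowSums(ys^2), "+") - 2 * tcrossprod(xs, ys)
  d2[d2 < 0] <- 0
  k <- params$signal_variance * exp(-0.5 * d2)
  if (length(k) == 1L) k[1L] else k
}

# Cholesky with an escalating jitter on the diagonal. Jitter starts at
# 1e-10 * signal_variance and grows tenfold up to 1e-6 * signal_variance.
chol_with_jitter <- function(K, signal_variance) {
  for (jit in signal_variance * c(0, 10^seq(-10, -6))) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
  }
  stop("Gram matrix could not be factorized even with jitter", call. = FALSE)
}

# negative log marginal likelihood of a zero-mean GP, via Cholesky
gp_nlml <- function(theta, X, y, noise_variance) {
  sv <- exp(theta[1L])
  ls <- exp(theta[-1L])
  params <- se_kernel_params(sv, ls)
  K <- se_kernel(X, X, params) + diag(noise_variance, nrow(X))
  f <- tryCatch(chol_with_jitter(K, sv), error = function(e) NULL)
  if (is.null(f)) return(1e10)
  L <- f$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) +
               0.5 * length(y) * log(2 * pi))
}

standardize_inputs <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

dataset_inputs <- function(ds) {
  cbind(pressure_bar = ds$pressure_bar, temperature_K = ds$temperature_K)
}

#' Fit a Gaussian process regressor
#'
#' Zero-mean Gaussian process regression of mole-fraction solubility on
#' (pressure, temperature) with the squared-exponential kernel. Inputs are
#' standardized to zero mean and unit variance per dimension internally;
#' targets are modelled in raw mole fraction. The observation noise
#' variance defaults to zero, so the fitted GP interpolates the training
#' data.
#'
#' Hyperparameters (signal variance and one length scale per input) are
#' chosen by maximizing the log marginal likelihood (ML-II), either by
#' multi-start quasi-Newton optimization in log-hyperparameter space
#' (`"ml2_multistart"`, default 8 seeded restarts) or by exhaustive
#' evaluation over a log-spaced grid (`"grid"`).
#'
#' @param ds a [solubility_dataset] with at least 2 records.
#' @param kernel0 starting [se_kernel_params()] (standardized-input scale);
#'   defaults to signal variance `var(y)` and unit length scales.
#' @param noise_variance observation noise variance sigma_n^2, >= 0.
#'   Default 0.
#' @param strategy `"ml2_multistart"` or `"grid"`.
#' @param n_restarts number of multi-start restarts (ml2_multistart).
#' @param grid optional named list `signal_variance`, `length_scale_P`,
#'   `length_scale_T` of candidate values for the `"grid"` strategy;
#'   defaults to a 12 x 10 x 10 log-spaced grid.
#' @param isotropic if `TRUE`, a single shared length scale is used.
#' @param seed integer seed for the restart draws.
#' @return An object of class `gpr_model`.
#' @examples
#' ds <- decitabine_dataset()
#' fit <- gpr_fit(ds, seed = 1)
#' predict(fit, data.frame(pressure_bar = 400, temperature_K = 338))
#' @export
gpr_fit <- function(ds, kernel0 = NULL, noise_variance = 0,
                    strategy = c("ml2_multistart", "grid"),
                    n_restarts = 8L, grid = NULL, isotropic = FALSE,
                    seed = 1L) {
  stopifnot(inherits(ds, "solubility_dataset"))
  strategy <- match.arg(strategy)
  if (nrow(ds) < 2L) stop("GPR needs at least 2 records", call. = FALSE)
  if (noise_variance < 0) stop("noise_variance must be >= 0", call. = FALSE)
  std <- standardize_inputs(dataset_inputs(ds))
  X <- std$X
  y <- ds$solubility_molefrac
  d <- if (isotropic) 1L else ncol(X)
  sv0 <- if (is.null(kernel0)) max(stats::var(y), 1e-12)
         else kernel0$signal_variance
  ls0 <- if (is.null(kernel0)) rep(1, d)
         else rep_len(kernel0$length_scale, d)
  theta0 <- c(log(sv0), log(ls0))

  if (strategy == "ml2_multistart") {
    set.seed(as.integer(seed))
    starts <- rbind(theta0,
                    if (n_restarts > 1L)
                      t(replicate(n_restarts - 1L,
                                  theta0 + stats::runif(d + 1L, -2, 2))))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(starts[i, ], gp_nlml, X = X, y = y,
                     noise_variance = noise_variance, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best))
      stop("all ML-II restarts failed to factorize the Gram matrix",
           call. = FALSE)
    theta <- best$par
  } else {
    if (is.null(grid))
      grid <- list(signal_variance = sv0 * 10^seq(-3, 3, length.out = 12),
                   length_scale_P = 10^seq(-1.5, 1.5, length.out = 10),
                   length_scale_T = 10^seq(-1.5, 1.5, length.out = 10))
    combos <- expand.grid(sv = grid$signal_variance,
                          lP = grid$length_scale_P,
                          lT = grid$length_scale_T)
    scores <- vapply(seq_len(nrow(combos)), function(i) {
      ls <- if (isotropic) combos$lP[i] else c(combos$lP[i], combos$lT[i])
      gp_nlml(log(c(combos$sv[i], ls)), X, y, noise_variance)
    }, numeric(1))
    i <- which.min(scores)
    theta <- log(c(combos$sv[i],
                   if (isotropic) combos$lP[i] else c(combos$lP[i], combos$lT[i])))
  }

  params <- se_kernel_params(exp(theta[1L]), exp(theta[-1L]))
  K <- se_kernel(X, X, params) + diag(noise_variance, nrow(X))
  f <- chol_with_jitter(K, params$signal_variance)
  alpha <- backsolve(f$L, forwardsolve(t(f$L), y))
  structure(list(kernel = params, noise_variance = noise_variance,
                 x_center = std$center, x_scale = std$scale,
                 X = X, y = y, L = f$L, jitter = f$jitter, alpha = alpha,
                 log_marginal_likelihood = -gp_nlml(theta, X, y,
                                                    noise_variance)),
            class = "gpr_model")
}

#' Log marginal likelihood of a fitted GP
#'
#' @param model a `gpr_model`.
#' @return The log marginal likelihood of the training targets under the
#'   fitted hyperparameters.
#' @export
log_marginal_likelihood <- function(model) {
  stopifnot(inherits(model, "gpr_model"))
  model$log_marginal_likelihood
}

#' Predict from a Gaussian process regressor
#'
#' Posterior mean K_* K^-1 y and predictive variance
#' K_** - K_* K^-1 K_*^T at new (pressure, temperature) points. The
#' variance quantifies the uncertainty of each prediction; it is zero (to
#' numerical tolerance) at training points when the noise variance is zero.
#'
#' @param object a fitted `gpr_model`.
#' @param newdata data.frame with columns `pressure_bar` and
#'   `temperature_K`.
#' @param ... unused.
#' @return A data.frame with columns `mean` and `variance` (variance
#'   clipped to be non-negative).
#' @export
predict.gpr_model <- function(object, newdata, ...) {
  if (is.null(object$L)) stop("model is not fitted", call. = FALSE)
  Xs <- standardize_inputs(
    cbind(newdata$pressure_bar, newdata$temperature_K),
    center = object$x_center, scale = object$x_scale)$X
  Ks <- se_kernel(Xs, object$X, object$kernel)
  Ks <- matrix(Ks, nrow = nrow(Xs))
  mean <- as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Ks))
  variance <- object$kernel$signal_variance - colSums(v^2)
  variance <- pmax(variance, 0)
  data.frame(mean = mean, variance = variance)
}

#' Fit a kernel ridge regressor
#'
#' Kernel ridge regression of solubility on standardized (pressure,
#' temperature): the minimizer over an RKHS of
#' (1/N) sum_i (f(x_i) - y_i)^2 + lambda ||f||_H^2, obtained in dual form
#' as alpha = (K + N lambda I)^-1 y with f(x) = sum_i alpha_i k(x, x_i).
#'
#' With N lambda equal to a GP's noise variance and the same kernel, the
#' KRR prediction coincides with the GP posterior mean.
#'
#' @param ds a [solubility_dataset].
#' @param kernel an [se_kernel_params()] (standardized-input scale).
#' @param lambda positive regularization constant.
#' @return An object of class `krr_model`.
#' @export
krr_fit <- function(ds, kernel = se_kernel_params(), lambda = 1e-4) {
  stopifnot(inherits(ds, "solubility_dataset"),
            inherits(kernel, "se_kernel_params"))
  if (!is.numeric(lambda) || lambda <= 0)
    stop("lambda must be positive", call. = FALSE)
  std <- standardize_inputs(dataset_inputs(ds))
  X <- std$X
  y <- ds$solubility_molefrac
  N <- nrow(X)
  K <- se_kernel(X, X, kernel)
  K <- matrix(K, nrow = N)
  alpha <- solve(K + diag(N * lambda, N), y)
  structure(list(kernel = kernel, lambda = lambda,
                 x_center = std$center, x_scale = std$scale,
                 X = X, y = y, alpha = as.numeric(alpha)),
            class = "krr_model")
}

#' Predict from a kernel ridge regressor
#'
#' @param object a fitted `krr_model`.
#' @param newdata data.frame with columns `pressure_bar` and
#'   `temperature_K`.
#' @param ... unused.
#' @return Numeric vector of predicted mole fractions.
#' @export
predict.krr_model <- function(object, newdata, ...) {
  if (is.null(object$alpha)) stop("model is not fitted", call. = FALSE)
  Xs <- standardize_inputs(
    cbind(newdata$pressure_bar, newdata$temperature_K),
    center = object$x_center, scale = object$x_scale)$X
  Ks <- matrix(se_kernel(Xs, object$X, object$kernel), nrow = nrow(Xs))
  as.numeric(Ks %*% object$alpha)
}
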