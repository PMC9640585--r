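#' Configure a synthetic solubility dataset
#'
#' Describes a ground-truth solubility surface y(T, P) plus a noise model,
#' from which reproducible datasets with known truth can be generated for
#' parameter-recovery and stress tests. The defaults emulate the structure
#' of the bundled decitabine data: the Kumar-Johnston surface with
#' parameters (7.32, -7108.7, 0.00769) evaluated over the full factorial
#' 8 x 4 grid of 120-400 bar and 308-338 K, giving mole fractions spanning
#' roughly 1e-5 to 1e-3, with 10\% multiplicative lognormal noise.
#' Multiplicative lognormal noise is the natural error model here because
#' solubilities are strictly positive and span orders of magnitude.
#'
#' @param form ground-truth surface: a registered correlation form id
#'   (e.g. `"kumar_johnston"`, `"bartle"`) or `"smooth_gp"`, which draws a
#'   random smooth log-solubility surface from a seeded GP prior to
#'   stress-test models beyond correlation-shaped truths.
#' @param params true correlation parameters (ignored for `smooth_gp`).
#' @param pressures,temperatures grid axes (bar, K); the full factorial
#'   grid is used.
#' @param noise_sd lognormal sigma of the multiplicative noise
#'   (fraction, >= 0).
#' @param seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(form = "kumar_johnston",
                             params = c(7.32, -7108.7, 0.00769),
                             pressures = seq(120, 400, by = 40),
                             temperatures = seq(308, 338, by = 10),
                             noise_sd = 0.10, seed = 1L) {
  stopifnot(noise_sd >= 0, length(pressures) >= 1L,
            length(temperatures) >= 1L)
  if (form != "smooth_gp") {
    f <- correlation_form(form)
    if (length(params) != f$arity)
      stop("form '", form, "' takes ", f$arity, " parameters", call. = FALSE)
  }
  structure(list(form = form, params = as.numeric(params),
                 pressures = as.numeric(pressures),
                 temperatures = as.numeric(temperatures),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic solubility dataset with known ground truth
#'
#' Evaluates the configured true surface on the (P, T) grid and applies
#' i.i.d. multiplicative lognormal noise: y_i = y_true(T_i, P_i) exp(e_i),
#' e_i ~ Normal(0, noise_sd^2). Identical seeds give identical datasets.
#'
#' @param config a [synthetic_config()].
#' @param provider [density_provider()] used to evaluate density-based
#'   truths.
#' @return A list with `dataset` (a [solubility_dataset]) and `truth`
#'   (list echoing the form, parameters, noise level, seed and the
#'   noise-free surface values).
#' @export
generate_solubility <- function(config, provider = density_provider()) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- expand.grid(temperature_K = config$temperatures,
                   pressure_bar = config$pressures)
  set.seed(config$seed)
  if (config$form == "smooth_gp") {
    # draw log-solubility from a smooth GP prior centred at ln(1e-4)
    X <- standardize_inputs(cbind(g$pressure_bar, g$temperature_K))$X
    K <- se_kernel(X, X, se_kernel_params(1, 1))
    L <- t(chol_with_jitter(K, 1)$L)
    y_true <- exp(log(1e-4) + as.numeric(L %*% stats::rnorm(nrow(g))))
  } else {
    rho <- co2_density(g$temperature_K, g$pressure_bar,
                       provider)$density_kg_m3
    y_true <- evaluate_correlation(config$form, config$params,
                                   g$temperature_K, g$pressure_bar, rho)
  }
  eps <- stats::rnorm(nrow(g), 0, config$noise_sd)
  y <- y_true * exp(eps)
  if (any(y <= 0 | y >= 1))
    stop("generated solubility falls outside (0, 1); ",
         "adjust the ground-truth parameters or noise level", call. = FALSE)
  list(dataset = solubility_dataset(g$pressure_bar, g$temperature_K, y,
                                    name = sprintf("synthetic (%s, sigma=%g)",
                                                   config$form,
                                                   config$noise_sd)),
       truth = list(form = config$form, params = config$params,
                    noise_sd = config$noise_sd, seed = config$seed,
                    y_true = y_true))
}

#' Parameter-recovery study on synthetic data
#'
#' Repeatedly generates datasets from the configured truth (fresh seed per
#' replicate) and refits the true correlation form, summarizing how well
#' the parameters are recovered.
#'
#' @param config a [synthetic_config()] with a correlation-form truth.
#' @param n_replicates number of replicates (>= 1).
#' @param provider [density_provider()].
#' @param objective,n_starts passed to [fit_correlation()].
#' @return An object of class `recovery_study`: list with `params`
#'   (replicate x parameter matrix of estimates), `aard` (per-replicate
#'   fitted AARD\%), `bias` (mean relative bias per parameter), `rmse`
#'   (root-mean-square error per parameter), `mean_aard`, `n_failed`.
#' @export
recovery_study <- function(config, n_replicates = 50L,
                           provider = density_provider(),
                           objective = "aard", n_starts = 8L) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1L,
            config$form != "smooth_gp")
  est <- matrix(NA_real_, n_replicates, length(config$params))
  aard <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    gen <- generate_solubility(cfg, provider)
    fit <- tryCatch(
      fit_correlation(gen$dataset, config$form, provider,
                      objective = objective, n_starts = n_starts,
                      seed = cfg$seed),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est[r, ] <- fit$params
      aard[r] <- fit$aard
    }
  }
  ok <- !is.na(aard)
  if (!any(ok)) stop("all replicate fits failed", call. = FALSE)
  rel_err <- sweep(sweep(est[ok, , drop = FALSE], 2L, config$params),
                   2L, config$params, "/")
  structure(list(params = est, aard = aard,
                 bias = colMeans(rel_err),
                 rmse = sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2L,
                                            config$params)^2)),
                 mean_aard = mean(aard[ok]),
                 n_failed = sum(!ok), truth = config$params),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("<recovery_study> %d replicates (%d failed)\n",
              nrow(x$params), x$n_failed))
  cat("  relative bias:", format(x$bias, digits = 3), "\n")
  cat(sprintf("  mean fitted AARD: %.2f%%\n", x$mean_aard))
  invisible(x)
}
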