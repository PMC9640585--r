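#' Squared-correlation R2
#'
#' The R2 statistic used throughout the package is the squared Pearson
#' correlation between observed and estimated values:
#' \deqn{R^2 = \frac{(\sum_i (Y_{i,m}-\bar Y_m)(Y_{i,o}-\bar Y_o))^2}
#'   {\sum_i (Y_{i,m}-\bar Y_m)^2 \sum_i (Y_{i,o}-\bar Y_o)^2}.}
#' It is invariant under affine transformation of either argument and lies
#' in [0, 1]. The familiar coefficient of determination
#' 1 - SS_res/SS_tot, which does penalize bias and scale, is available as
#' [coefficient_of_determination()].
#'
#' @param observed,estimated numeric vectors of equal length >= 2, each
#'   with nonzero variance.
#' @return The squared correlation.
#' @export
r_squared <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated))
  if (length(observed) < 2L)
    stop("R2 needs at least two observations", call. = FALSE)
  do <- observed - mean(observed)
  de <- estimated - mean(estimated)
  sso <- sum(do^2); sse <- sum(de^2)
  if (sso == 0 || sse == 0)
    stop("R2 is undefined when either sequence has zero variance",
         call. = FALSE)
  sum(do * de)^2 / (sso * sse)
}

#' Coefficient of determination 1 - SS_res/SS_tot
#'
#' @inheritParams r_squared
#' @return 1 - sum((obs - est)^2) / sum((obs - mean(obs))^2); can be
#'   negative for models worse than the constant mean.
#' @export
coefficient_of_determination <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("undefined when the observations have zero variance", call. = FALSE)
  1 - sum((observed - estimated)^2) / sst
}

#' Error metrics
#'
#' `mae` is the mean absolute error (1/n) sum |Y_m - Y_o|. `mape` is the
#' mean absolute relative error (1/n) sum |Y_m - Y_o| / |Y_o|, reported as
#' a dimensionless fraction. `aard_percent` is 100 * mape, the average
#' absolute relative deviation in percent used to rank solubility
#' correlations.
#'
#' @param observed,estimated numeric vectors of equal length >= 1; for
#'   `mape`/`aard_percent` every observed value must be nonzero.
#' @return A non-negative scalar.
#' @export
mae <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated), length(observed) >= 1L)
  mean(abs(estimated - observed))
}

#' @rdname mae
#' @export
mape <- function(observed, estimated) {
  stopifnot(length(observed) == length(estimated), length(observed) >= 1L)
  zero <- which(observed == 0)
  if (length(zero))
    stop("MAPE undefined: observed value is zero at position ", zero[1L],
         call. = FALSE)
  mean(abs(estimated - observed) / abs(observed))
}

#' @rdname mae
#' @export
aard_percent <- function(observed, estimated) 100 * mape(observed, estimated)

#' Predict solubility from any fitted model
#'
#' A common prediction interface over the model families in the package
#' (GPR, KRR, regression tree, fitted correlation). Returns the point
#' prediction (for GPR, the posterior mean).
#'
#' @param model a fitted model object.
#' @param pressure numeric vector, bar.
#' @param temperature numeric vector, kelvin (recycled against pressure).
#' @return Numeric vector of predicted mole fractions.
#' @export
predict_solubility <- function(model, pressure, temperature) {
  UseMethod("predict_solubility")
}

#' @export
predict_solubility.gpr_model <- function(model, pressure, temperature) {
  n <- max(length(pressure), length(temperature))
  nd <- data.frame(pressure_bar = rep_len(pressure, n),
                   temperature_K = rep_len(temperature, n))
  predict(model, nd)$mean
}

#' @export
predict_solubility.krr_model <- function(model, pressure, temperature) {
  n <- max(length(pressure), length(temperature))
  nd <- data.frame(pressure_bar = rep_len(pressure, n),
                   temperature_K = rep_len(temperature, n))
  predict(model, nd)
}

#' @export
predict_solubility.solubility_tree <- function(model, pressure, temperature) {
  n <- max(length(pressure), length(temperature))
  nd <- data.frame(pressure_bar = rep_len(pressure, n),
                   temperature_K = rep_len(temperature, n))
  predict(model, nd)
}

#' @export
predict_solubility.correlation_model <- function(model, pressure,
                                                 temperature) {
  n <- max(length(pressure), length(temperature))
  p <- rep_len(pressure, n); tk <- rep_len(temperature, n)
  rho <- co2_density(tk, p, model$provider)$density_kg_m3
  evaluate_correlation(model$form, model$params, tk, p, rho)
}

#' Evaluate a fitted model on a dataset
#'
#' @param model any model supported by [predict_solubility()].
#' @param ds a [solubility_dataset].
#' @return An object of class `metrics_report`: a list with `r2`
#'   (squared-correlation R2), `mae`, `mape` (fraction), `aard_percent`
#'   and `n`.
#' @export
evaluate_model <- function(model, ds) {
  stopifnot(inherits(ds, "solubility_dataset"))
  est <- predict_solubility(model, ds$pressure_bar, ds$temperature_K)
  obs <- ds$solubility_molefrac
  structure(list(r2 = r_squared(obs, est), mae = mae(obs, est),
                 mape = mape(obs, est),
                 aard_percent = aard_percent(obs, est), n = nrow(ds)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n  R2 = %.4f  MAE = %.3e  MAPE = %.3e  AARD = %.2f%%\n",
              x$n, x$r2, x$mae, x$mape, x$aard_percent))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' Grids used by [grid_search()] when none is supplied; each spans more
#' than 1000 combinations.
#'
#' @param family `"gpr"`, `"krr"` or `"tree"`.
#' @return A named list of candidate vectors.
#' @export
default_grid <- function(family = c("gpr", "krr", "tree")) {
  family <- match.arg(family)
  switch(family,
    gpr = list(signal_variance_scale = 10^seq(-3, 3, length.out = 12),
               length_scale_P = 10^seq(-1.5, 1.5, length.out = 10),
               length_scale_T = 10^seq(-1.5, 1.5, length.out = 10)),
    krr = list(lambda = 10^seq(-10, -1, length.out = 36),
               length_scale = 10^seq(-1.5, 1.5, length.out = 30)),
    tree = list(max_depth = 1:12, min_samples_leaf = 1:8,
                min_samples_split = 2:12))
}

fit_family <- function(family, train, combo) {
  switch(family,
    gpr = {
      sv <- combo$signal_variance_scale *
        max(stats::var(train$solubility_molefrac), 1e-12)
      gpr_fit(train,
              kernel0 = se_kernel_params(sv, c(combo$length_scale_P,
                                               combo$length_scale_T)),
              strategy = "grid",
              grid = list(signal_variance = sv,
                          length_scale_P = combo$length_scale_P,
                          length_scale_T = combo$length_scale_T))
    },
    krr = krr_fit(train, se_kernel_params(1, combo$length_scale),
                  lambda = combo$lambda),
    tree = fit_tree(train, tree_config(max_depth = combo$max_depth,
                                       min_samples_leaf = combo$min_samples_leaf,
                                       min_samples_split = combo$min_samples_split)))
}

#' Exhaustive grid search over hyperparameters
#'
#' Fits the chosen model family at every combination of the candidate
#' grid and scores it, either on the full data (default), on a random
#' holdout, or by k-fold cross-validation. The returned best combination
#' is the one minimizing the error metric (`"mape"`, `"mae"`,
#' `"aard_percent"`) or maximizing `"r2"`. Failed fits are recorded with
#' an `NA` score and skipped.
#'
#' @param ds a [solubility_dataset].
#' @param family `"gpr"`, `"krr"` or `"tree"`.
#' @param grid named list of candidate vectors; defaults to
#'   [default_grid()] for the family.
#' @param metric scoring metric name.
#' @param split `"full_data"`, `"holdout"` or `"kfold"`.
#' @param test_fraction holdout fraction (split = "holdout").
#' @param k number of folds (split = "kfold").
#' @param seed seed for holdout/fold assignment.
#' @return A list with `best` (named list of the winning hyperparameters),
#'   `best_score`, and `results` (data.frame of every combination with its
#'   score).
#' @export
grid_search <- function(ds, family = c("gpr", "krr", "tree"), grid = NULL,
                        metric = c("mape", "mae", "aard_percent", "r2"),
                        split = c("full_data", "holdout", "kfold"),
                        test_fraction = 0.25, k = 4L, seed = 1L) {
  family <- match.arg(family)
  metric <- match.arg(metric)
  split <- match.arg(split)
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(length(grid) >= 1L, all(lengths(grid) >= 1L))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)

  metric_fun <- switch(metric, mape = mape, mae = mae,
                       aard_percent = aard_percent, r2 = r_squared)
  score_combo <- function(combo) {
    if (split == "full_data") {
      m <- fit_family(family, ds, combo)
      est <- predict_solubility(m, ds$pressure_bar, ds$temperature_K)
      metric_fun(ds$solubility_molefrac, est)
    } else if (split == "holdout") {
      sp <- split_dataset(ds, test_fraction, seed)
      m <- fit_family(family, sp$train, combo)
      est <- predict_solubility(m, sp$test$pressure_bar,
                                sp$test$temperature_K)
      metric_fun(sp$test$solubility_molefrac, est)
    } else {
      set.seed(as.integer(seed))
      fold <- sample(rep_len(seq_len(k), nrow(ds)))
      vals <- vapply(seq_len(k), function(f) {
        tr <- solubility_dataset(ds$pressure_bar[fold != f],
                                 ds$temperature_K[fold != f],
                                 ds$solubility_molefrac[fold != f])
        te <- ds[fold == f, , drop = FALSE]
        m <- fit_family(family, tr, combo)
        est <- predict_solubility(m, te$pressure_bar, te$temperature_K)
        metric_fun(te$solubility_molefrac, est)
      }, numeric(1))
      mean(vals)
    }
  }
  scores <- vapply(seq_len(nrow(combos)), function(i)
    tryCatch(score_combo(as.list(combos[i, , drop = FALSE])),
             error = function(e) NA_real_),
    numeric(1))
  results <- cbind(combos, score = scores)
  if (all(is.na(scores))) stop("every grid combination failed", call. = FALSE)
  best_i <- if (metric == "r2") which.max(scores) else which.min(scores)
  list(best = as.list(combos[best_i, , drop = FALSE]),
       best_score = scores[best_i], results = results, metric = metric)
}

#' Predict a solubility response surface
#'
#' @param model any model supported by [predict_solubility()].
#' @param pressure numeric vector of grid pressures (bar).
#' @param temperature numeric vector of grid temperatures (K).
#' @return A data.frame in row-major order (temperature varying fastest)
#'   with columns `pressure_bar`, `temperature_K`, `mean`, and, for GPR
#'   models, `variance`.
#' @export
predict_surface <- function(model, pressure, temperature) {
  stopifnot(length(pressure) >= 1L, length(temperature) >= 1L,
            all(pressure > 0), all(temperature > 0))
  g <- expand.grid(temperature_K = temperature, pressure_bar = pressure)
  g <- g[, c("pressure_bar", "temperature_K")]
  rownames(g) <- NULL
  if (inherits(model, "gpr_model")) {
    pr <- predict(model, g)
    cbind(g, mean = pr$mean, variance = pr$variance)
  } else {
    cbind(g, mean = predict_solubility(model, g$pressure_bar,
                                       g$temperature_K))
  }
}

#' Locate the solubility optimum over a (P, T) domain
#'
#' Grid argmax of the predicted solubility, refined by bounded local
#' ascent (L-BFGS-B) from the best grid point and clipped to the domain.
#' The search domain defaults to the training data's bounding box, since
#' predictions degrade outside the data hull.
#'
#' @param model any model supported by [predict_solubility()].
#' @param pressure_range,temperature_range length-2 numeric domains.
#' @param resolution grid points per axis for the initial scan.
#' @return An object of class `optimum_result`: list with `pressure_bar`,
#'   `temperature_K`, `solubility`.
#' @export
find_optimum <- function(model, pressure_range = c(120, 400),
                         temperature_range = c(308, 338),
                         resolution = 41L) {
  stopifnot(length(pressure_range) == 2L, length(temperature_range) == 2L,
            diff(pressure_range) >= 0, diff(temperature_range) >= 0)
  ps <- seq(pressure_range[1L], pressure_range[2L], length.out = resolution)
  ts <- seq(temperature_range[1L], temperature_range[2L],
            length.out = resolution)
  surf <- predict_surface(model, ps, ts)
  i <- which.max(surf$mean)
  x0 <- c(surf$pressure_bar[i], surf$temperature_K[i])
  obj <- function(x) -predict_solubility(model, x[1L], x[2L])
  ref <- tryCatch(
    stats::optim(x0, obj, method = "L-BFGS-B",
                 lower = c(pressure_range[1L], temperature_range[1L]),
                 upper = c(pressure_range[2L], temperature_range[2L])),
    error = function(e) list(par = x0, value = obj(x0)))
  if (-ref$value < surf$mean[i]) ref <- list(par = x0, value = -surf$mean[i])
  structure(list(pressure_bar = ref$par[1L], temperature_K = ref$par[2L],
                 solubility = -ref$value),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("<optimum_result> P = %.1f bar, T = %.1f K, y = %.6g\n",
              x$pressure_bar, x$temperature_K, x$solubility))
  invisible(x)
}

#' Crossover pressure between two isotherms
#'
#' Solubility isotherms at two temperatures typically intersect: below the
#' crossover pressure raising the temperature lowers solubility (the CO2
#' density loss dominates), above it raising the temperature increases
#' solubility (the solute vapor-pressure gain dominates). This function
#' locates the sign change of `delta(P) = y(T2, P) - y(T1, P)`.
#'
#' Given a fitted model, the pressure axis is scanned and the first sign
#' change refined by bisection. Given a dataset, the two measured
#' isotherms are compared at their common pressures and the bracketing
#' pair of pressures is reported (no interpolation beyond the data).
#'
#' @param object a fitted model or a [solubility_dataset].
#' @param T1,T2 the two temperatures (K), `T1 < T2`.
#' @param pressure_range length-2 pressure scan range (bar); for datasets,
#'   defaults to the measured range.
#' @param n number of scan points for model curves.
#' @return An object of class `crossover_result`: list with `T1`, `T2`,
#'   `crossover_pressure` (bar, or `NA` if the isotherms do not cross),
#'   `bracket` (length-2 pressures enclosing the sign change, or `NULL`),
#'   and `sign_pattern` (signs of delta across the scanned pressures).
#' @export
crossover_pressure <- function(object, T1, T2,
                               pressure_range = c(120, 400), n = 201L) {
  stopifnot(T1 < T2)
  if (inherits(object, "solubility_dataset")) {
    d1 <- object[object$temperature_K == T1, ]
    d2 <- object[object$temperature_K == T2, ]
    ps <- sort(intersect(d1$pressure_bar, d2$pressure_bar))
    if (length(ps) < 2L)
      stop("datasets need at least two common pressures on both isotherms",
           call. = FALSE)
    delta <- d2$solubility_molefrac[match(ps, d2$pressure_bar)] -
      d1$solubility_molefrac[match(ps, d1$pressure_bar)]
  } else {
    ps <- seq(pressure_range[1L], pressure_range[2L], length.out = n)
    delta <- predict_solubility(object, ps, T2) -
      predict_solubility(object, ps, T1)
  }
  sgn <- sign(delta)
  flip <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0L) {
    res <- list(T1 = T1, T2 = T2, crossover_pressure = NA_real_,
                bracket = NULL, sign_pattern = sgn, pressures = ps)
  } else {
    i <- flip[1L]
    bracket <- c(ps[i], ps[i + 1L])
    pc <- if (inherits(object, "solubility_dataset")) NA_real_ else
      stats::uniroot(function(p) predict_solubility(object, p, T2) -
                       predict_solubility(object, p, T1),
                     interval = bracket, tol = 1e-6)$root
    res <- list(T1 = T1, T2 = T2, crossover_pressure = pc,
                bracket = bracket, sign_pattern = sgn, pressures = ps)
  }
  structure(res, class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  if (is.null(x$bracket)) {
    cat(sprintf("<crossover_result> T = %g vs %g K: no crossover in range\n",
                x$T1, x$T2))
  } else if (is.na(x$crossover_pressure)) {
    cat(sprintf("<crossover_result> T = %g vs %g K: crossover between %g and %g bar\n",
                x$T1, x$T2, x$bracket[1L], x$bracket[2L]))
  } else {
    cat(sprintf("<crossover_result> T = %g vs %g K: crossover at %.1f bar\n",
                x$T1, x$T2, x$crossover_pressure))
  }
  invisible(x)
}
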