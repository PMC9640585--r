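#' @title Density-based semi-empirical solubility correlations
#' @description Registry of correlation forms. Two classical forms ship
#' built in:
#' \describe{
#'   \item{kumar_johnston}{`ln y = a0 + a1/T + a2 rho`, with rho in
#'     kg/m^3; 3 parameters.}
#'   \item{bartle}{`ln(y P / P_ref) = a0 + a1/T + a2 (rho - rho_ref)` with
#'     `P_ref = 1` bar and `rho_ref = 700` kg/m^3; 3 parameters.}
#' }
#' Further forms (e.g. the five- and six-parameter correlations of Bian
#' and of Sodeifian) can be added with [register_correlation_form()] once
#' their exact equations are available; no guessed equation is shipped.
#' @name correlation_forms
NULL

.correlation_registry <- new.env(parent = emptyenv())

#' Register a correlation form
#'
#' @param id short identifier for the form.
#' @param arity number of adjustable parameters.
#' @param evaluator `function(params, temperature, pressure, density)`
#'   returning predicted mole fractions.
#' @param overwrite replace an existing registration.
#' @return `id`, invisibly.
#' @export
register_correlation_form <- function(id, arity, evaluator,
                                      overwrite = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, is.function(evaluator),
            arity >= 1)
  if (!overwrite && exists(id, envir = .correlation_registry))
    stop("correlation form '", id, "' is already registered", call. = FALSE)
  assign(id, list(id = id, arity = as.integer(arity), evaluator = evaluator),
         envir = .correlation_registry)
  invisible(id)
}

correlation_form <- function(id) {
  if (!exists(id, envir = .correlation_registry))
    stop("unknown correlation form '", id, "'; registered forms: ",
         paste(sort(ls(.correlation_registry)), collapse = ", "),
         call. = FALSE)
  get(id, envir = .correlation_registry)
}

#' Registered correlation forms
#' @return Character vector of registered form ids.
#' @export
correlation_form_ids <- function() sort(ls(.correlation_registry))

# built-in forms; reference constants for Bartle are the literature
# convention P_ref = 1 bar, rho_ref = 700 kg/m^3
BARTLE_P_REF <- 1
BARTLE_RHO_REF <- 700

register_builtin_forms <- function() {
  register_correlation_form("kumar_johnston", 3L,
    function(params, temperature, pressure, density)
      exp(params[1L] + params[2L] / temperature + params[3L] * density),
    overwrite = TRUE)
  register_correlation_form("bartle", 3L,
    function(params, temperature, pressure, density)
      exp(params[1L] + params[2L] / temperature +
            params[3L] * (density - BARTLE_RHO_REF)) *
        BARTLE_P_REF / pressure,
    overwrite = TRUE)
}
register_builtin_forms()

.onLoad <- function(libname, pkgname) register_builtin_forms()

#' Evaluate a correlation form
#'
#' @param form a registered form id, e.g. `"kumar_johnston"`.
#' @param params numeric parameter vector of the form's arity.
#' @param temperature kelvin.
#' @param pressure bar.
#' @param density CO2 density, kg/m^3 (positive).
#' @return Predicted mole-fraction solubility (vectorized).
#' @examples
#' rho <- co2_density(338, 400)$density_kg_m3
#' evaluate_correlation("kumar_johnston", c(7.32, -7108.7, 0.00769),
#'                      338, 400, rho)
#' @export
evaluate_correlation <- function(form, params, temperature, pressure,
                                 density) {
  f <- correlation_form(form)
  if (length(params) != f$arity)
    stop("form '", f$id, "' takes ", f$arity, " parameters, got ",
         length(params), call. = FALSE)
  if (any(density <= 0)) stop("density must be positive", call. = FALSE)
  y <- f$evaluator(params, temperature, pressure, density)
  if (any(!is.finite(y)))
    stop("correlation produced a non-finite solubility", call. = FALSE)
  y
}

# coarse linear-regression initialization in the form's own log space
correlation_init <- function(form, temperature, pressure, density, y) {
  if (form == "kumar_johnston")
    return(unname(stats::coef(stats::lm(log(y) ~ I(1 / temperature) + density))))
  if (form == "bartle")
    return(unname(stats::coef(stats::lm(
      log(y * pressure / BARTLE_P_REF) ~ I(1 / temperature) +
        I(density - BARTLE_RHO_REF)))))
  rep(0, correlation_form(form)$arity)
}

#' Fit a density-based correlation to solubility data
#'
#' Computes the CO2 density at every record via the density provider, then
#' adjusts the correlation parameters by multi-start local optimization.
#' The default objective is the average absolute relative deviation
#' AARD\% = (100/n) sum |y_calc - y_exp| / y_exp, the standard criterion
#' for solubility correlations; `"log_least_squares"` (sum of squared
#' residuals in ln y) is a better-conditioned alternative. Starts are
#' seeded perturbations of a coarse linear fit in the form's log space;
#' the best result across starts is kept, and never worse than that
#' initial guess.
#'
#' @param ds a [solubility_dataset].
#' @param form registered form id (default `"kumar_johnston"`).
#' @param provider a [density_provider()].
#' @param objective `"aard"` (default) or `"log_least_squares"`.
#' @param n_starts number of optimization starts (default 16).
#' @param seed integer seed for the start perturbations.
#' @return An object of class `correlation_model` with elements `form`,
#'   `params`, `aard` (percent), `r2`, `n`, and the provider used.
#' @examples
#' \donttest{
#' fit <- fit_correlation(decitabine_dataset(), "kumar_johnston", seed = 1)
#' fit$aard
#' }
#' @export
fit_correlation <- function(ds, form = "kumar_johnston",
                            provider = density_provider(),
                            objective = c("aard", "log_least_squares"),
                            n_starts = 16L, seed = 1L) {
  stopifnot(inherits(ds, "solubility_dataset"))
  objective <- match.arg(objective)
  f <- correlation_form(form)
  if (nrow(ds) <= f$arity)
    stop("need more records than parameters to fit '", form, "'",
         call. = FALSE)
  rho <- density_grid(ds, provider)$density_kg_m3
  y <- ds$solubility_molefrac
  Tk <- ds$temperature_K
  P <- ds$pressure_bar

  loss <- function(par) {
    yc <- tryCatch(f$evaluator(par, Tk, P, rho), error = function(e) NULL)
    if (is.null(yc) || any(!is.finite(yc)) || any(yc <= 0)) return(1e10)
    if (objective == "aard") 100 * mean(abs(yc - y) / y)
    else sum((log(yc) - log(y))^2)
  }

  init <- correlation_init(form, Tk, P, rho, y)
  set.seed(as.integer(seed))
  best_par <- init
  best_val <- loss(init)
  for (s in seq_len(n_starts)) {
    start <- if (s == 1L) init else init * (1 + 0.1 * stats::rnorm(f$arity))
    fit <- tryCatch({
      o <- stats::optim(start, loss, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
      stats::optim(o$par, loss, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12))
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$value < best_val) {
      best_val <- fit$value
      best_par <- fit$par
    }
  }
  if (!is.finite(best_val) || best_val >= 1e10)
    stop("correlation fit failed to converge in all starts (best objective ",
         best_val, ")", call. = FALSE)

  yc <- f$evaluator(best_par, Tk, P, rho)
  structure(list(form = form, params = as.numeric(best_par),
                 aard = 100 * mean(abs(yc - y) / y),
                 r2 = r_squared(y, yc),
                 objective = objective, n = nrow(ds),
                 provider = provider, fitted = yc),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> %s: AARD = %.2f%%, R2 = %.4f\n",
              x$form, x$aard, x$r2))
  cat("  params:", format(x$params, digits = 6), "\n")
  invisible(x)
}

#' Compare fitted correlation models
#'
#' @param models list of `correlation_model` objects.
#' @return A data.frame with one row per model (form, parameters a0..a5,
#'   AARD\%, R2), sorted by AARD ascending with ties broken by form name;
#'   the first row is the best model.
#' @export
correlation_report <- function(models) {
  if (inherits(models, "correlation_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "correlation_model")))
  pars <- t(vapply(models, function(m) {
    p <- rep(NA_real_, 6L)
    p[seq_along(m$params)] <- m$params
    p
  }, numeric(6)))
  colnames(pars) <- paste0("a", 0:5)
  out <- data.frame(form = vapply(models, `[[`, character(1), "form"),
                    pars,
                    aard_percent = vapply(models, `[[`, numeric(1), "aard"),
                    r2 = vapply(models, `[[`, numeric(1), "r2"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aard_percent, out$form), , drop = FALSE]
  rownames(out) <- NULL
  out
}
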