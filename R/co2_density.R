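#' Physical constants for carbon dioxide
#'
#' Critical temperature 304.13 K, critical pressure 73.77 bar, acentric
#' factor 0.224 and molar mass 44.01 g/mol.
#'
#' @return A named list of CO2 constants.
#' @export
co2_constants <- function() {
  list(T_c = 304.13,        # K
       P_c_bar = 73.77,     # bar
       acentric = 0.224,
       molar_mass = 44.01)  # g/mol
}

#' Define a CO2 density provider
#'
#' Density-based solubility correlations need the solvent density
#' rho(T, P). The default provider computes it from the Peng-Robinson cubic
#' equation of state; a `user_table` provider returns exactly the densities
#' supplied in `table`, so reference-quality values can be substituted.
#'
#' @param type `"peng_robinson"` (default) or `"user_table"`.
#' @param table for `user_table`: a data.frame with columns
#'   `temperature_K`, `pressure_bar`, `density_kg_m3`.
#' @param constants CO2 constants, see [co2_constants()].
#' @return An object of class `density_provider`.
#' @export
density_provider <- function(type = c("peng_robinson", "user_table"),
                             table = NULL, constants = co2_constants()) {
  type <- match.arg(type)
  stopifnot(all(unlist(constants) > 0))
  if (type == "user_table") {
    if (is.null(table) ||
        !all(c("temperature_K", "pressure_bar", "density_kg_m3") %in%
             names(table)))
      stop("user_table provider needs a table with columns ",
           "temperature_K, pressure_bar, density_kg_m3", call. = FALSE)
  }
  structure(list(type = type, table = table, constants = constants),
            class = "density_provider")
}

# Universal gas constant, J/(mol K)
.R_GAS <- 8.314462618

# Peng-Robinson pressure P(T, rho) in bar; the inverse of the density
# solve, used as a re-substitution check.
pr_pressure <- function(temperature, density, constants = co2_constants()) {
  M <- constants$molar_mass * 1e-3            # kg/mol
  v <- M / density                            # m^3/mol
  ab <- pr_ab(temperature, constants)
  P_pa <- .R_GAS * temperature / (v - ab$b) -
    ab$a_alpha / (v * (v + ab$b) + ab$b * (v - ab$b))
  P_pa / 1e5
}

pr_ab <- function(temperature, constants) {
  T_c <- constants$T_c
  P_c <- constants$P_c_bar * 1e5
  w <- constants$acentric
  a <- 0.45724 * .R_GAS^2 * T_c^2 / P_c
  b <- 0.07780 * .R_GAS * T_c / P_c
  kappa <- 0.37464 + 1.54226 * w - 0.26992 * w^2
  alpha <- (1 + kappa * (1 - sqrt(temperature / T_c)))^2
  list(a_alpha = a * alpha, b = b)
}

# log fugacity coefficient for a PR compressibility root; used to pick the
# stable phase below T_c (lower ln(phi) = lower Gibbs energy)
pr_log_phi <- function(Z, A, B) {
  (Z - 1) - log(Z - B) -
    A / (2 * sqrt(2) * B) * log((Z + (1 + sqrt(2)) * B) /
                                (Z + (1 - sqrt(2)) * B))
}

pr_density_one <- function(temperature, pressure_bar, constants) {
  P <- pressure_bar * 1e5
  ab <- pr_ab(temperature, constants)
  A <- ab$a_alpha * P / (.R_GAS^2 * temperature^2)
  B <- ab$b * P / (.R_GAS * temperature)
  # cubic in compressibility Z:
  # Z^3 - (1-B) Z^2 + (A - 3B^2 - 2B) Z - (AB - B^2 - B^3) = 0
  roots <- polyroot(c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1))
  Z <- Re(roots[abs(Im(roots)) < 1e-8 * max(1, Mod(roots))])
  Z <- sort(Z[Z > B])
  if (length(Z) == 0L)
    stop("no physical root of the equation of state", call. = FALSE)
  if (temperature >= constants$T_c || length(Z) == 1L) {
    Z_sel <- Z[length(Z)]
    phase <- if (temperature >= constants$T_c) "supercritical"
             else if (Z_sel == min(Z)) "subcritical_liquid" else "subcritical_vapor"
  } else {
    # two candidate phases: smallest root = liquid, largest = vapor
    Zl <- Z[1L]; Zv <- Z[length(Z)]
    if (pr_log_phi(Zl, A, B) <= pr_log_phi(Zv, A, B)) {
      Z_sel <- Zl; phase <- "subcritical_liquid"
    } else {
      Z_sel <- Zv; phase <- "subcritical_vapor"
    }
  }
  M <- constants$molar_mass * 1e-3
  rho <- P * M / (Z_sel * .R_GAS * temperature)
  if (rho <= 0 || rho >= 1600)
    stop("equation of state produced an unphysical CO2 density", call. = FALSE)
  # re-substitution guard: the returned density must reproduce P
  if (abs(pr_pressure(temperature, rho, constants) - pressure_bar) >
      1e-8 * pressure_bar)
    stop("equation-of-state root failed the pressure re-substitution check",
         call. = FALSE)
  list(density = rho, phase = phase)
}

#' CO2 density at given conditions
#'
#' Computes the density of CO2 at each (temperature, pressure) pair via the
#' configured provider. For the Peng-Robinson provider the real root of the
#' cubic equation of state appropriate to the phase is used: the unique
#' root in the supercritical region (T >= 304.13 K), otherwise the root
#' with the lower Gibbs energy (fugacity comparison). The returned density
#' reproduces the input pressure through the equation of state to a
#' relative tolerance of 1e-8.
#'
#' @param temperature numeric vector, kelvin (positive).
#' @param pressure numeric vector, bar (positive); recycled against
#'   `temperature`.
#' @param provider a [density_provider()].
#' @return A data.frame with columns `temperature_K`, `pressure_bar`,
#'   `density_kg_m3` and `phase`.
#' @examples
#' co2_density(308, 120)
#' @export
co2_density <- function(temperature, pressure,
                        provider = density_provider()) {
  stopifnot(inherits(provider, "density_provider"))
  n <- max(length(temperature), length(pressure))
  temperature <- rep_len(as.numeric(temperature), n)
  pressure <- rep_len(as.numeric(pressure), n)
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive", call. = FALSE)
  if (any(!is.finite(pressure)) || any(pressure <= 0))
    stop("pressure must be positive", call. = FALSE)
  if (provider$type == "user_table") {
    tab <- provider$table
    key <- paste(signif(temperature, 10), signif(pressure, 10))
    tab_key <- paste(signif(tab$temperature_K, 10), signif(tab$pressure_bar, 10))
    idx <- match(key, tab_key)
    if (anyNA(idx))
      stop("user_table provider has no entry for (",
           temperature[which(is.na(idx))[1L]], " K, ",
           pressure[which(is.na(idx))[1L]], " bar)", call. = FALSE)
    return(data.frame(temperature_K = temperature, pressure_bar = pressure,
                      density_kg_m3 = tab$density_kg_m3[idx],
                      phase = ifelse(temperature >= provider$constants$T_c,
                                     "supercritical", "subcritical_liquid"),
                      stringsAsFactors = FALSE))
  }
  out <- vapply(seq_len(n), function(i) {
    res <- pr_density_one(temperature[i], pressure[i], provider$constants)
    c(res$density, match(res$phase, c("supercritical", "subcritical_liquid",
                                      "subcritical_vapor")))
  }, numeric(2))
  data.frame(temperature_K = temperature, pressure_bar = pressure,
             density_kg_m3 = out[1L, ],
             phase = c("supercritical", "subcritical_liquid",
                       "subcritical_vapor")[out[2L, ]],
             stringsAsFactors = FALSE)
}

#' Densities over a dataset's (P, T) grid
#'
#' @param ds a [solubility_dataset].
#' @param provider a [density_provider()].
#' @return A data.frame with one row per record of `ds` (columns as in
#'   [co2_density()]), in dataset order.
#' @export
density_grid <- function(ds, provider = density_provider()) {
  if (nrow(ds) == 0L)
    return(data.frame(temperature_K = numeric(0), pressure_bar = numeric(0),
                      density_kg_m3 = numeric(0), phase = character(0)))
  co2_density(ds$temperature_K, ds$pressure_bar, provider)
}
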