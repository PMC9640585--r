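# Random valid solubility dataset on distinct (P, T) points
random_dataset <- function(n, seed) {
  set.seed(seed)
  p <- sample(seq(80, 500, by = 5), n)
  tk <- sample(seq(305, 345, by = 1), n, replace = TRUE)
  while (anyDuplicated(cbind(p, tk))) {
    dup <- duplicated(cbind(p, tk))
    tk[dup] <- tk[dup] + 0.5
  }
  y <- exp(runif(n, log(1e-5), log(1e-3)))
  solubility_dataset(p, tk, y, name = paste0("random-", seed))
}

# Independent Peng-Robinson pressure P(T, rho) [bar], written directly from
# the equation of state; used to verify density roots by re-substitution.
oracle_pr_pressure <- function(temperature, density) {
  R <- 8.314462618
  T_c <- 304.13; P_c <- 73.77e5; w <- 0.224; M <- 44.01e-3
  a <- 0.45724 * R^2 * T_c^2 / P_c
  b <- 0.07780 * R * T_c / P_c
  kappa <- 0.37464 + 1.54226 * w - 0.26992 * w^2
  a_alpha <- a * (1 + kappa * (1 - sqrt(temperature / T_c)))^2
  v <- M / density
  (R * temperature / (v - b) -
     a_alpha / (v * (v + b) + b * (v - b))) / 1e5
}

# Exhaustive brute-force search for the best first split of a dataset:
# every feature, every midpoint between consecutive sorted unique values.
oracle_best_split <- function(ds, criterion = "sd", min_leaf = 1L) {
  X <- cbind(ds$pressure_bar, ds$temperature_K)
  y <- ds$solubility_molefrac
  best <- NULL
  for (j in 1:2) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2L) next
    for (thr in (u[-length(u)] + u[-1]) / 2) {
      left <- X[, j] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      sc <- split_score(y[left], y[!left], criterion)
      if (is.null(best) || sc < best$score - 1e-15)
        best <- list(feature = j, threshold = thr, score = sc)
    }
  }
  best
}
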