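#' Regression tree configuration
#'
#' @param max_depth maximum tree depth (root at depth 0); `Inf` grows until
#'   the other limits bind.
#' @param min_samples_leaf minimum records in any leaf (default 1).
#' @param min_samples_split minimum records a node needs to be considered
#'   for splitting (default 2).
#' @param criterion node-impurity scale used in the split score:
#'   `"sd"` scores a split as the child-size-weighted sum of population
#'   standard deviations; `"variance"` uses population variances (the
#'   classical CART mean-squared-error reduction). Both pick the split
#'   minimizing the weighted child impurity.
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(max_depth = Inf, min_samples_leaf = 1L,
                        min_samples_split = 2L,
                        criterion = c("sd", "variance")) {
  criterion <- match.arg(criterion)
  stopifnot(max_depth >= 0, min_samples_leaf >= 1, min_samples_split >= 2)
  structure(list(max_depth = max_depth,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 min_samples_split = as.integer(min_samples_split),
                 criterion = criterion),
            class = "tree_config")
}

# population standard deviation s(t) = sqrt((1/N) sum (c_i - mean)^2)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Score a candidate split
#'
#' The split score is the child-size-weighted impurity
#' p_L s(t_L) + p_R s(t_R), where p_side = N(side)/N and s(t) is the
#' population standard deviation of the targets in t (`criterion = "sd"`,
#' default) or their population variance (`criterion = "variance"`).
#' Lower is better.
#'
#' @param left,right numeric target values on each side of the split; both
#'   must be nonempty.
#' @param criterion `"sd"` or `"variance"`.
#' @return The split score.
#' @examples
#' split_score(c(0, 0), c(1, 1))   # pure split, 0
#' split_score(c(0, 1), c(0, 1))   # 0.5
#' @export
split_score <- function(left, right, criterion = c("sd", "variance")) {
  criterion <- match.arg(criterion)
  if (length(left) == 0L || length(right) == 0L)
    stop("both sides of a split must be nonempty", call. = FALSE)
  n <- length(left) + length(right)
  imp <- if (criterion == "sd") pop_sd else function(x) pop_sd(x)^2
  (length(left) / n) * imp(left) + (length(right) / n) * imp(right)
}

# best (feature, threshold) at a node, or NULL if no admissible split.
# Candidate thresholds are midpoints between consecutive sorted unique
# feature values. Ties broken by feature order (P before T), then by the
# smaller threshold.
best_split <- function(X, y, config) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2L) next
    for (thr in (u[-length(u)] + u[-1L]) / 2) {
      left <- X[, j] <= thr
      if (sum(left) < config$min_samples_leaf ||
          sum(!left) < config$min_samples_leaf) next
      sc <- split_score(y[left], y[!left], config$criterion)
      if (is.null(best) || sc < best$score - 1e-15)
        best <- list(feature = j, threshold = thr, score = sc)
    }
  }
  best
}

grow_tree <- function(X, y, config, depth) {
  n <- length(y)
  if (depth >= config$max_depth || n < config$min_samples_split ||
      pop_sd(y) == 0)
    return(list(leaf = TRUE, value = mean(y), n = n))
  sp <- best_split(X, y, config)
  if (is.null(sp)) return(list(leaf = TRUE, value = mean(y), n = n))
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE,
       feature = colnames(X)[sp$feature], threshold = sp$threshold, n = n,
       left = grow_tree(X[left, , drop = FALSE], y[left], config, depth + 1L),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], config,
                         depth + 1L))
}

#' Fit a regression tree
#'
#' Greedy recursive binary partitioning of the (pressure, temperature)
#' space. At each node every candidate (feature, midpoint-threshold) pair
#' is scored with [split_score()] and the minimizer is taken; recursion
#' stops at the depth limit, at nodes below the sample-size limits, or at
#' zero-variance nodes. Leaves predict the arithmetic mean of their
#' training targets.
#'
#' @param ds a [solubility_dataset].
#' @param config a [tree_config()].
#' @return An object of class `solubility_tree`.
#' @examples
#' tr <- fit_tree(decitabine_dataset())
#' predict(tr, data.frame(pressure_bar = 240, temperature_K = 328))
#' @export
fit_tree <- function(ds, config = tree_config()) {
  stopifnot(inherits(ds, "solubility_dataset"),
            inherits(config, "tree_config"))
  X <- dataset_inputs(ds)
  root <- grow_tree(X, ds$solubility_molefrac, config, 0L)
  structure(list(root = root, config = config, n = nrow(ds)),
            class = "solubility_tree")
}

route <- function(node, p, t) {
  while (!node$leaf) {
    x <- if (node$feature == "pressure_bar") p else t
    node <- if (x <= node$threshold) node$left else node$right
  }
  node$value
}

#' Predict from a regression tree
#'
#' Each point is routed from the root by threshold comparisons
#' (value <= threshold goes left) until a leaf is reached; the leaf mean is
#' returned.
#'
#' @param object a fitted `solubility_tree`.
#' @param newdata data.frame with columns `pressure_bar` and
#'   `temperature_K`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.solubility_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)),
         function(i) route(object$root, newdata$pressure_bar[i],
                           newdata$temperature_K[i]),
         numeric(1))
}

#' @export
print.solubility_tree <- function(x, ...) {
  count_leaves <- function(node)
    if (node$leaf) 1L else count_leaves(node$left) + count_leaves(node$right)
  cat(sprintf("<solubility_tree> %d training records, %d leaves\n",
              x$n, count_leaves(x$root)))
  invisible(x)
}
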