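#' Serialize a fitted model to JSON
#'
#' Writes a self-contained JSON description of a fitted model:
#' hyperparameters, input standardization constants and dual coefficients
#' for the kernel models; the nested node structure (split feature,
#' threshold, children, leaf values and counts) for trees; form id and
#' parameters for correlations. [read_model_json()] restores a functional
#' model.
#'
#' @param model a `gpr_model`, `krr_model`, `solubility_tree` or
#'   `correlation_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "gpr_model")) {
    list(type = "gpr_model",
         kernel = list(signal_variance = model$kernel$signal_variance,
                       length_scale = model$kernel$length_scale),
         noise_variance = model$noise_variance,
         x_center = as.numeric(model$x_center),
         x_scale = as.numeric(model$x_scale),
         X = unclass(as.data.frame(model$X)), y = model$y,
         alpha = model$alpha)
  } else if (inherits(model, "krr_model")) {
    list(type = "krr_model",
         kernel = list(signal_variance = model$kernel$signal_variance,
                       length_scale = model$kernel$length_scale),
         lambda = model$lambda,
         x_center = as.numeric(model$x_center),
         x_scale = as.numeric(model$x_scale),
         X = unclass(as.data.frame(model$X)), y = model$y,
         alpha = model$alpha)
  } else if (inherits(model, "solubility_tree")) {
    cfg <- unclass(model$config)
    if (!is.finite(cfg$max_depth)) cfg$max_depth <- -1  # -1 encodes unlimited
    list(type = "solubility_tree", n = model$n, config = cfg,
         root = model$root)
  } else if (inherits(model, "correlation_model")) {
    list(type = "correlation_model", form = model$form,
         params = model$params, aard = model$aard, r2 = model$r2, n = model$n,
         provider_type = model$provider$type)
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns the restored model object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type %in% c("gpr_model", "krr_model")) {
    kern <- se_kernel_params(obj$kernel$signal_variance,
                             obj$kernel$length_scale)
    X <- as.matrix(as.data.frame(obj$X))
    colnames(X) <- c("pressure_bar", "temperature_K")
    if (obj$type == "gpr_model") {
      K <- se_kernel(X, X, kern) + diag(obj$noise_variance, nrow(X))
      f <- chol_with_jitter(K, kern$signal_variance)
      structure(list(kernel = kern, noise_variance = obj$noise_variance,
                     x_center = obj$x_center, x_scale = obj$x_scale,
                     X = X, y = obj$y, L = f$L, jitter = f$jitter,
                     alpha = obj$alpha,
                     log_marginal_likelihood = NA_real_),
                class = "gpr_model")
    } else {
      structure(list(kernel = kern, lambda = obj$lambda,
                     x_center = obj$x_center, x_scale = obj$x_scale,
                     X = X, y = obj$y, alpha = obj$alpha),
                class = "krr_model")
    }
  } else if (obj$type == "solubility_tree") {
    cfg <- tree_config(max_depth = if (obj$config$max_depth < 0) Inf
                                   else obj$config$max_depth,
                       min_samples_leaf = obj$config$min_samples_leaf,
                       min_samples_split = obj$config$min_samples_split,
                       criterion = obj$config$criterion)
    structure(list(root = obj$root, config = cfg, n = obj$n),
              class = "solubility_tree")
  } else if (obj$type == "correlation_model") {
    structure(list(form = obj$form, params = obj$params, aard = obj$aard,
                   r2 = obj$r2, n = obj$n,
                   provider = density_provider(obj$provider_type)),
              class = "correlation_model")
  } else stop("unknown model type '", obj$type, "'", call. = FALSE)
}
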