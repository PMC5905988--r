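#' Pipeline configuration
#'
#' Collects every tunable of the measurement pipeline in one object: the
#' profile model, the centerline and spline settings, the CLR-rule
#' thresholds, the regressor hyperparameters, the validation scheme and the
#' master seed. All randomness in a run flows from `seed` (the regressor
#' seed and fold assignment are derived from it unless set explicitly).
#'
#' @param model Profile model: `"dogl7"` (default), `"dogl8"` or
#'   `"hermite"`.
#' @param min_segment_length Minimum centerline segment length in pixels
#'   (default 10).
#' @param spline_spacing Pixels of centerline per spline piece (default 20).
#' @param neighbors Cross-section profiles pooled per fit (default 11).
#' @param clr_rules [clr_rules()] thresholds.
#' @param regressor [regressor_config()] hyperparameters.
#' @param validation `"kfold"` or `"loso"`.
#' @param k Folds for cross-validation (default 10).
#' @param seed Master seed.
#' @param standard_gaussian Use the conventional Gaussian exponent in the
#'   models (default `FALSE`, the models' printed form).
#' @param verbose Emit per-stage log messages (default `TRUE`).
#' @return List of class `vc_config`.
#' @export
vc_config <- function(model = "dogl7", min_segment_length = 10,
                      spline_spacing = 20, neighbors = 11,
                      clr_rules = vesselcaliber::clr_rules(),
                      regressor = regressor_config(),
                      validation = c("kfold", "loso"), k = 10, seed = 1,
                      standard_gaussian = FALSE, verbose = TRUE) {
  model <- match.arg(model, model_ids())
  validation <- match.arg(validation)
  regressor$seed <- regressor$seed %||% seed
  structure(
    list(model = model, min_segment_length = min_segment_length,
         spline_spacing = spline_spacing, neighbors = neighbors,
         clr_rules = clr_rules, regressor = regressor,
         validation = validation, k = k, seed = seed,
         standard_gaussian = standard_gaussian, verbose = verbose),
    class = "vc_config"
  )
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as human-readable YAML key-value files; keys
#' absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @param config A [vc_config()] object.
#' @return `read_config()` returns a `vc_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- vc_config()
  for (nm in intersect(names(raw), setdiff(names(cfg), c("clr_rules", "regressor")))) {
    cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$clr_rules)) {
    cfg$clr_rules <- do.call(clr_rules, utils::modifyList(
      lapply(unclass(clr_rules()), identity), raw$clr_rules))
  }
  if (!is.null(raw$regressor)) {
    cfg$regressor <- do.call(regressor_config, utils::modifyList(
      list(n_trees = 100, predictors_per_split = NULL, min_leaf = 5, seed = cfg$seed),
      raw$regressor))
  }
  cfg$model <- match.arg(cfg$model, model_ids())
  cfg$validation <- match.arg(cfg$validation, c("kfold", "loso"))
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vc_config"))
  out <- unclass(config)
  out$clr_rules <- unclass(out$clr_rules)
  out$regressor <- unclass(out$regressor)
  out$regressor <- out$regressor[!vapply(out$regressor, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
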