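## YAML experiment configuration: every tolerance and protocol constant in
## one nested list, overridable from a file.

#' Default pipeline configuration
#'
#' Nested per-module list holding the protocol constants (25 slices from
#' 20% above the apex, 256x256 masks at 1 mm, 50-pixel exclusion, 2 mm
#' valve clearance), the tuned training hyperparameters, and the
#' synthetic-cohort defaults.
#'
#' @return nested list of class `lvscar_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(n_slices = 25L, apex_offset = 0.20, size = 256L,
                    resolution = 1, min_pixels = 50L, valve_tol = 2.0),
    polar = list(size = 256L, radial_resolution = 1, pad = TRUE),
    synthetic = list(n_patients = 10L, scar_prevalence = 0.5,
                     size_range = c(75, 95), wall_thickness_range = c(8, 12),
                     modality_perturbation = 0.19, shape_noise = 0.02,
                     scar = list(angular_extent = 80, axial_extent = 0.35,
                                 center_axial = 0.45, thinning_factor = 0.5,
                                 taper = 0.3, shape_noise = 0.05)),
    registration = list(max_iter = 200L, tol = 1e-4, n_sample = 600L,
                        translation_only = FALSE),
    classifier = list(architecture = "vgg_small",
                      learning_rate = 0.009, momentum = 0.73,
                      batch_size = 10L, gamma = 1.560, alpha = 0.6,
                      epochs_cv = 100L, epochs_final = 500L,
                      k_folds = 10L, prediction_threshold = 0.5),
    evaluation = list(n_boot = 2000L, ci_level = 0.95, band = "percentile"),
    seed = 1L), class = "lvscar_config")
}

#' Load a configuration from YAML, merged over the defaults
#'
#' @param path YAML file; keys present in the file override the defaults,
#'   all others keep their default values.
#' @return nested list of class `lvscar_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, override) {
    for (k in names(override)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
        merge_lists(base[[k]], override[[k]]) else override[[k]]
    }
    base
  }
  structure(merge_lists(unclass(cfg), user), class = "lvscar_config")
}

#' Write a configuration to YAML
#' @param config an `lvscar_config`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build a [cohort_spec()] from a pipeline configuration
#' @param config an `lvscar_config`.
#' @param n_patients,seed optional overrides.
#' @return a [cohort_spec()].
#' @export
config_cohort_spec <- function(config, n_patients = NULL, seed = NULL) {
  s <- config$synthetic
  cohort_spec(n_patients = if (is.null(n_patients)) s$n_patients else n_patients,
              scar_prevalence = s$scar_prevalence,
              size_range = s$size_range,
              wall_thickness_range = s$wall_thickness_range,
              scar = scar_spec(angular_extent = s$scar$angular_extent,
                               axial_extent = s$scar$axial_extent,
                               center_axial = s$scar$center_axial,
                               thinning_factor = s$scar$thinning_factor,
                               taper = s$scar$taper,
                               shape_noise = s$scar$shape_noise),
              modality_perturbation = s$modality_perturbation,
              shape_noise = s$shape_noise,
              seed = if (is.null(seed)) config$seed else seed)
}

#' Build a [train_config()] from a pipeline configuration
#' @param config an `lvscar_config`.
#' @param epochs,seed optional overrides.
#' @return a [train_config()].
#' @export
config_train_config <- function(config, epochs = NULL, seed = NULL) {
  cl <- config$classifier
  train_config(learning_rate = cl$learning_rate, momentum = cl$momentum,
               batch_size = cl$batch_size,
               epochs = if (is.null(epochs)) cl$epochs_cv else epochs,
               loss = focal_loss_params(cl$gamma, cl$alpha),
               seed = if (is.null(seed)) config$seed else seed,
               prediction_threshold = cl$prediction_threshold)
}
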