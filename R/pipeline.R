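## End-to-end orchestration: training flow (cohort -> CV report -> final
## model) and independent-test flow (registration-transferred ground truth,
## leakage guard), with a reproducibility manifest.

#' Content fingerprint of an R object
#'
#' MD5 of the version-3 serialization; used for train/test leakage checks
#' and run manifests.
#'
#' @param x any serializable object.
#' @return hex string.
#' @export
fingerprint <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(x, NULL, version = 3L), tf)
  unname(tools::md5sum(tf))
}

cohort_fingerprints <- function(cohort, modality = "mri") {
  vapply(cohort$patients,
         function(p) fingerprint(p[[modality]]$epi$vertices),
         character(1L), USE.NAMES = FALSE) |>
    stats::setNames(vapply(cohort$patients, `[[`, character(1L), "patient_id"))
}

#' Run the training flow
#'
#' Meshes -> axes -> slices -> masks -> polar -> patient-wise folds ->
#' cross-validation -> final full-data retrain.  Returns the trained final
#' model, the cross-validation report and a run manifest (config snapshot,
#' seeds, per-patient input fingerprints, stage timings, slice retention
#' counts).
#'
#' @param cohort an `lv_cohort` (the MRI-like meshes are used).
#' @param config an `lvscar_config` from [default_config()].
#' @param seed master seed.
#' @param epochs_cv,epochs_final epoch overrides (defaults from config:
#'   100 per fold, 500 final).
#' @param k_folds fold override.
#' @param n_boot bootstrap resamples for the report.
#' @return list of class `training_flow`: `model`, `cv`, `dataset`,
#'   `manifest`.
#' @export
run_training_flow <- function(cohort, config = default_config(), seed = config$seed,
                              epochs_cv = NULL, epochs_final = NULL,
                              k_folds = NULL, n_boot = NULL) {
  g <- config$geometry
  cl <- config$classifier
  if (is.null(epochs_cv)) epochs_cv <- cl$epochs_cv
  if (is.null(epochs_final)) epochs_final <- cl$epochs_final
  if (is.null(k_folds)) k_folds <- cl$k_folds
  if (is.null(n_boot)) n_boot <- config$evaluation$n_boot
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  dataset <- cohort_to_dataset(cohort, "mri", "native",
                               n_slices = g$n_slices, apex_offset = g$apex_offset,
                               valve_tol = g$valve_tol, size = g$size,
                               resolution = g$resolution,
                               min_pixels = g$min_pixels)
  timings["slicing"] <- tic() - t0

  retention <- stats::aggregate(valid ~ patient_id, dataset$info, sum)
  dropped <- retention$patient_id[retention$valid == 0L]
  if (length(dropped) > 0L) {
    warning("patients with no retained slices dropped: ",
            paste(dropped, collapse = ", "))
    dataset <- dataset[!(dataset$info$patient_id %in% dropped)]
  }

  cfg_cv <- config_train_config(config, epochs = epochs_cv, seed = seed)
  t0 <- tic()
  cv <- cross_validate(dataset, cfg_cv, k = k_folds,
                       architecture = cl$architecture, seed = seed,
                       n_boot = n_boot)
  timings["cross_validation"] <- tic() - t0

  cfg_final <- config_train_config(config, epochs = epochs_final, seed = seed)
  t0 <- tic()
  model <- scar_cnn(dataset, cfg_final, architecture = cl$architecture,
                    seed = seed)
  timings["final_training"] <- tic() - t0

  manifest <- list(config = unclass(config), seed = seed,
                   epochs_cv = epochs_cv, epochs_final = epochs_final,
                   k_folds = k_folds,
                   fingerprints = as.list(cohort_fingerprints(cohort, "mri")),
                   retention = retention,
                   n_valid = sum(dataset$info$valid),
                   n_scar = sum(dataset$info$label[dataset$info$valid] == 1L),
                   timings = as.list(timings),
                   tool_version = as.character(utils::packageVersion("lvscar")))
  structure(list(model = model, cv = cv, dataset = dataset,
                 manifest = manifest),
            class = "training_flow")
}

#' @export
print.training_flow <- function(x, ...) {
  cat(sprintf("training flow: %d valid slices (%d scar)\n",
              x$manifest$n_valid, x$manifest$n_scar))
  print(x$cv$report)
  invisible(x)
}

#' Run the independent-test flow
#'
#' The target-modality (CTA-like) meshes are sliced and encoded with the
#' identical protocol; ground truth comes from registering each source
#' mesh onto its paired target ([icp_register()]), transferring the scar
#' mesh, and labeling the target slices against it.  A fingerprint
#' intersection check enforces that no test mesh was seen in training.
#'
#' @param model a fitted `scar_cnn`.
#' @param cohort the paired `lv_cohort` providing target meshes and source
#'   scars.
#' @param config an `lvscar_config`.
#' @param train_fingerprints named fingerprint vector from the training
#'   manifest (leakage guard; skipped when `NULL` with a warning).
#' @param n_boot bootstrap resamples for the report.
#' @return list of class `test_flow`: `report`, `dataset`, `transforms`,
#'   `transfer_agreement` (fraction of slices whose transferred label
#'   matches the native one).
#' @export
run_test_flow <- function(model, cohort, config = default_config(),
                          train_fingerprints = NULL, n_boot = NULL) {
  g <- config$geometry
  r <- config$registration
  if (is.null(n_boot)) n_boot <- config$evaluation$n_boot
  test_fp <- cohort_fingerprints(cohort, "cta")
  if (is.null(train_fingerprints)) {
    warning("no training fingerprints supplied; leakage check skipped")
  } else {
    overlap <- intersect(unname(train_fingerprints), unname(test_fp))
    if (length(overlap) > 0L) {
      ids <- names(test_fp)[test_fp %in% overlap]
      stop("train/test leakage: test mesh also present in training set for patient ",
           paste(ids, collapse = ", "))
    }
  }
  rows <- list(); cols <- list(); transforms <- list()
  agree_n <- 0L; agree_tot <- 0L
  for (p in cohort$patients) {
    scar_t <- NULL
    if (!is.null(p$mri$scar)) {
      tr <- icp_register(p$mri, p$cta, max_iter = r$max_iter, tol = r$tol,
                         n_sample = r$n_sample)
      transforms[[p$patient_id]] <- tr
      scar_t <- transfer_scar(p$mri$scar, tr)
    }
    samples <- slice_patient(p$cta, scar_mesh = scar_t,
                             n_slices = g$n_slices, apex_offset = g$apex_offset,
                             valve_tol = g$valve_tol, size = g$size,
                             resolution = g$resolution,
                             min_pixels = g$min_pixels)
    native <- slice_patient_labels(p$cta, g)
    for (s in samples) {
      agree_tot <- agree_tot + 1L
      if (s$label == native[s$slice_index + 1L]) agree_n <- agree_n + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, slice_index = s$slice_index,
        normalized_position = s$normalized_position, label = s$label,
        valid = s$valid, reason = s$reason, n_pixels = s$n_pixels,
        stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- if (is.null(s$polar))
        raw(g$size^2) else mask_to_raw(s$polar$grid)
    }
  }
  dataset <- new_slice_dataset(do.call(rbind, rows), do.call(cbind, cols),
                               g$size)
  ds <- valid_samples(dataset)
  probs <- predict(model, ds)
  rep <- eval_report(probs, ds$info$label,
                     threshold = model$config$prediction_threshold,
                     n_boot = n_boot)
  structure(list(report = rep, dataset = dataset, probabilities = probs,
                 transforms = transforms,
                 transfer_agreement = agree_n / agree_tot),
            class = "test_flow")
}

# native per-plane labels of a mesh's own scar, aligned to the protocol
slice_patient_labels <- function(mesh, g) {
  protocol_labels(mesh, n_slices = g$n_slices, apex_offset = g$apex_offset)$label
}

#' @export
print.test_flow <- function(x, ...) {
  cat(sprintf("independent test flow (transferred-label agreement %.1f%%):\n",
              100 * x$transfer_agreement))
  print(x$report)
  invisible(x)
}

#' Write a run manifest to JSON
#' @param manifest the `manifest` element of a [run_training_flow()] result.
#' @param path output file.
#' @param deterministic drop stage timings so reruns are byte-identical.
#' @return `path` invisibly.
#' @export
write_manifest <- function(manifest, path, deterministic = FALSE) {
  if (deterministic) manifest$timings <- NULL
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
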