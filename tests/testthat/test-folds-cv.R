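# fold assignment, cross-validation hygiene, PSO and the thickness baseline

fake_dataset <- function(info, size = 4L) {
  new_slice_dataset(info, matrix(as.raw(0L), size^2, nrow(info)), size)
}

test_that("fold assignment is patient-wise with no leakage", {
  info <- data.frame(patient_id = rep(sprintf("P%02d", 1:20), each = 10L),
                     slice_index = rep(0:9, 20L),
                     normalized_position = rep(seq(0.2, 1, length.out = 10L), 20L),
                     label = rep(c(1L, 0L), c(3L, 7L)),
                     valid = TRUE, reason = "none", n_pixels = 500L)
  ds <- fake_dataset(info)
  folds <- make_folds(ds, k = 10L, seed = 1)
  expect_identical(sort(unique(as.integer(folds))), 1:10)
  expect_true(all(table(as.integer(folds)) == 2L))
  # every patient in exactly one fold
  expect_identical(length(folds), 20L)
  expect_false(any(duplicated(names(folds))))
  expect_error(make_folds(ds, k = 30L), "patients")
})

test_that("scar-free cohorts partition without balance warnings", {
  info <- data.frame(patient_id = rep(sprintf("P%02d", 1:12), each = 5L),
                     slice_index = 0L, normalized_position = 0.5,
                     label = 0L, valid = TRUE, reason = "none", n_pixels = 500L)
  expect_no_warning(folds <- make_folds(fake_dataset(info), k = 4L, seed = 2))
  expect_identical(sort(unique(as.integer(folds))), 1:4)
})

test_that("an adversarial scar concentration triggers the balance warning", {
  # patient HOT holds 10 of 19 scar slices (> 50%)
  info <- data.frame(patient_id = rep(c("HOT", sprintf("P%02d", 1:9)),
                                      each = 10L),
                     slice_index = 0L, normalized_position = 0.5,
                     label = c(rep(1L, 10L), rep(c(1L, rep(0L, 9L)), 9L)),
                     valid = TRUE, reason = "none", n_pixels = 500L)
  expect_warning(folds <- make_folds(fake_dataset(info), k = 5L, seed = 3),
                 "deviate")
  # exhaustive balance recomputation agrees with the reported table
  tab <- attr(folds, "table")
  for (j in seq_len(5L)) {
    pats <- names(folds)[folds == j]
    sel <- info$patient_id %in% pats
    expect_identical(sum(sel), as.integer(tab$n_slices[j]))
    expect_identical(sum(info$label[sel] == 1L), as.integer(tab$n_scar[j]))
  }
})

test_that("cross-validation predicts every valid slice exactly once", {
  coh <- generate_cohort(cohort_spec(n_patients = 6, seed = 19))
  ds <- cohort_to_dataset(coh, "mri", "native")
  cv <- suppressWarnings(
    cross_validate(ds, train_config(epochs = 1L), k = 3L, seed = 2,
                   n_boot = 50L))
  expect_false(any(is.na(cv$info$probability)))
  expect_identical(nrow(cv$info), sum(ds$info$valid))
  key <- paste(cv$info$patient_id, cv$info$slice_index)
  expect_false(any(duplicated(key)))
  # patient-wise: each patient appears in exactly one fold
  expect_identical(nrow(unique(cv$info[, c("patient_id", "fold")])), 6L)
  # report consistency identity: acc = (sens n+ + spec n-) / n
  r <- cv$report
  np <- r$n_positive; nn <- r$n_samples - np
  expect_equal(r$accuracy,
               (r$sensitivity * np + r$specificity * nn) / r$n_samples,
               tolerance = 1e-12)
})

test_that("constant calls score at the majority-class fraction", {
  labels <- c(rep(1L, 3L), rep(0L, 7L))
  expect_equal(accuracy(rep(0L, 10L), labels), 0.7)
  expect_equal(accuracy(rep(1L, 10L), labels), 0.3)
})

test_that("PSO locates a known quadratic optimum and is seed-deterministic", {
  target <- c(x = 0.3, y = -1.2)
  obj <- function(p) -(p[["x"]] - 0.3)^2 - 2 * (p[["y"]] + 1.2)^2
  sw <- swarm_config(n_particles = 15L, iterations = 50L,
                     bounds = list(x = c(-2, 2), y = c(-3, 3)), seed = 8)
  res <- pso_optimize(obj, sw)
  expect_lt(abs(res$par[["x"]] - 0.3), 0.01 * 4)     # 1% of range
  expect_lt(abs(res$par[["y"]] + 1.2), 0.01 * 6)
  expect_true(all(diff(res$trace) >= 0))             # global best is monotone
  res2 <- pso_optimize(obj, sw)
  expect_identical(res$trace, res2$trace)
  expect_error(pso_optimize(obj, swarm_config(bounds = list())), "empty")
})

test_that("the default swarm bounds bracket the shipped training defaults", {
  b <- swarm_config()$bounds
  cfg <- train_config()
  expect_true(b$learning_rate[1L] <= cfg$learning_rate &&
                cfg$learning_rate <= b$learning_rate[2L])
  expect_true(b$momentum[1L] <= cfg$momentum && cfg$momentum <= b$momentum[2L])
  expect_true(b$batch_size[1L] <= cfg$batch_size &&
                cfg$batch_size <= b$batch_size[2L])
  expect_true(b$gamma[1L] <= cfg$loss$gamma && cfg$loss$gamma <= b$gamma[2L])
  expect_true(b$alpha[1L] <= cfg$loss$alpha && cfg$loss$alpha <= b$alpha[2L])
})

test_that("hyperparameter tuning wires PSO positions into train configs", {
  # cheap objective on the config (no training): prefers lr near 0.01
  obj <- function(cfg) -(cfg$learning_rate - 0.01)^2 -
    (cfg$batch_size - 10L)^2 / 1000
  res <- tune_hyperparameters(dataset = NULL,
                              swarm = swarm_config(n_particles = 10L,
                                                   iterations = 25L, seed = 2),
                              objective = obj)
  expect_s3_class(res$config, "train_config")
  expect_lt(abs(res$config$learning_rate - 0.01), 0.002)
  expect_identical(res$config$batch_size, 10L)
  expect_true(is.integer(res$config$batch_size))
})

test_that("thickness baseline measures walls and orders by thinness", {
  pm_thick <- band_polar_mask(20L, 10L)
  pm_thin <- band_polar_mask(22L, 10L, sector = c(40L, 70L), sector_thick = 4L)
  expect_equal(min_wall_thickness(pm_thick), 10, tolerance = 1)
  expect_equal(min_wall_thickness(pm_thin), 4, tolerance = 1)
  n <- 30L
  set.seed(3)
  labels <- sample(0:1, n, TRUE)
  masks <- vapply(labels, function(l) {
    pm <- if (l == 1L) band_polar_mask(sample(16:26, 1), 10L, sector = c(40, 70),
                                       sector_thick = 4L)
    else band_polar_mask(sample(16:26, 1), 10L)
    as.raw(as.integer(pm$grid))
  }, raw(256^2))
  info <- data.frame(patient_id = sprintf("P%02d", seq_len(n)), slice_index = 0L,
                     normalized_position = 0.5, label = labels, valid = TRUE,
                     reason = "none", n_pixels = 100L)
  ds <- new_slice_dataset(info, masks, 256L)
  tb <- thickness_baseline(ds)
  expect_identical(tb$calls, labels)          # perfectly separable by design
  expect_equal(roc_auc(tb$score, labels)$auc, 1)
})
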