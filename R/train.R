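## Training, patient-wise balanced cross-validation, PSO tuning, and the
## wall-thickness baseline.

#' Training configuration
#'
#' Defaults are the tuned hyperparameters: learning rate 0.009, momentum
#' 0.73, batch size 10, focal loss gamma 1.560 / alpha 0.6, 100 epochs per
#' cross-validation fold (500 for the final full-data retrain).
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param loss a [focal_loss_params()].
#' @param seed integer seed (weight init and shuffling).
#' @param prediction_threshold probability threshold for positive calls
#'   (calls are `p >= threshold`).
#' @param augment_shift random circular shift of the angular axis of each
#'   training sample (in polar coordinates an in-plane rotation is exactly
#'   a column rotation, so this is free rotation augmentation); on by
#'   default.
#' @param oversample_positive duplicate positive (scar) slices so the
#'   classes are near-balanced within the training set; off by default
#'   (the focal-loss alpha weighting already addresses imbalance).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.009, momentum = 0.73,
                         batch_size = 10L, epochs = 100L,
                         loss = focal_loss_params(), seed = 1L,
                         prediction_threshold = 0.5, augment_shift = TRUE,
                         oversample_positive = FALSE) {
  if (learning_rate <= 0 || momentum < 0 || batch_size < 1L || epochs < 1L)
    stop("learning_rate, batch_size and epochs must be positive")
  if (prediction_threshold <= 0 || prediction_threshold >= 1)
    stop("prediction_threshold must be in (0, 1)")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 seed = as.integer(seed),
                 prediction_threshold = prediction_threshold,
                 augment_shift = isTRUE(augment_shift),
                 oversample_positive = isTRUE(oversample_positive)),
            class = "train_config")
}

#' Fit the slice-classification CNN
#'
#' Trains a VGG-style convolutional network on the valid slices of a polar
#' mask dataset with stochastic gradient descent (momentum) under focal
#' loss.  This is the package's central fitting function; the returned
#' object supports `print`, `summary`, `predict` and `plot`.
#'
#' @param dataset a `slice_dataset` (only valid slices are used), or a raw
#'   mask matrix with `labels` supplied.
#' @param config a [train_config()].
#' @param architecture `"vgg_small"` (default) or `"vgg16"`.
#' @param labels binary labels when `dataset` is a raw matrix.
#' @param seed seed; defaults to `config$seed`.
#' @return object of class `scar_cnn`.
#' @export
scar_cnn <- function(dataset, config = train_config(),
                     architecture = "vgg_small", labels = NULL,
                     seed = config$seed) {
  if (inherits(dataset, "slice_dataset")) {
    ds <- valid_samples(dataset)
    masks <- ds$masks
    labels <- ds$info$label
    size <- ds$size
  } else {
    masks <- dataset
    size <- as.integer(sqrt(nrow(masks)))
    if (is.null(labels)) stop("labels required for a raw mask matrix")
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; focal-loss weighting is meaningless")
  if (isTRUE(config$oversample_positive)) {
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 < n0) {
      extra <- rep(which(labels == 1L), length.out = n0 - n1)
      masks <- cbind(masks, masks[, extra, drop = FALSE])
      labels <- c(labels, labels[extra])
    }
  }
  spec <- network_spec(architecture, size)
  net <- build_network(spec, seed)
  fit <- cnn_train_cpp(layer_matrix(spec), net$weights, masks, size, size,
                       labels,
                       config$learning_rate, config$momentum,
                       config$batch_size, config$epochs,
                       config$loss$gamma, config$loss$alpha, seed,
                       isTRUE(config$augment_shift))
  structure(list(spec = spec, weights = fit$weights, config = config,
                 loss_trace = fit$loss, acc_trace = fit$train_accuracy,
                 n_samples = length(labels), n_positive = sum(labels == 1L),
                 seed = as.integer(seed)),
            class = "scar_cnn")
}

#' Predict scar probabilities for new slices
#'
#' @param object a fitted `scar_cnn`.
#' @param newdata a `slice_dataset`, a raw mask matrix, or a single
#'   `polar_mask`.
#' @param type `"prob"` for probabilities, `"class"` for binary calls.
#' @param threshold decision threshold (default from the training config);
#'   a probability equal to the threshold is called positive.
#' @param ... ignored.
#' @return numeric probabilities or integer calls, in input order.
#' @export
predict.scar_cnn <- function(object, newdata, type = c("prob", "class"),
                             threshold = object$config$prediction_threshold,
                             ...) {
  type <- match.arg(type)
  masks <- if (inherits(newdata, "slice_dataset")) newdata$masks
  else if (inherits(newdata, "polar_mask")) {
    matrix(mask_to_raw(newdata$grid), ncol = 1L)
  } else newdata
  if (nrow(masks) != object$spec$input_size^2)
    stop(sprintf("mask size %d does not match network input %d^2",
                 nrow(masks), object$spec$input_size))
  p <- network_forward(list(spec = object$spec, weights = object$weights),
                       masks)
  if (type == "prob") p else as.integer(p >= threshold)
}

#' @export
print.scar_cnn <- function(x, ...) {
  cat(sprintf("scar_cnn (%s): trained on %d slices (%d scar), %d epochs\n",
              x$spec$architecture, x$n_samples, x$n_positive,
              length(x$loss_trace)))
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              x$loss_trace[length(x$loss_trace)],
              x$acc_trace[length(x$acc_trace)]))
  invisible(x)
}

#' @export
summary.scar_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %s; lr %.4g, momentum %.2f, batch %d, gamma %.3f, alpha %.2f\n",
              format(n_parameters(object), big.mark = ","),
              object$config$learning_rate, object$config$momentum,
              object$config$batch_size, object$config$loss$gamma,
              object$config$loss$alpha))
  invisible(object)
}

#' @export
plot.scar_cnn <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "mean focal loss", main = "training loss", ...)
  invisible(x)
}

#' Patient-wise balanced fold assignment
#'
#' Partitions patients into `k` folds so that all slices of a patient fall
#' in one fold and each fold's scar-slice fraction stays close to the
#' global fraction: patients are assigned greedily in decreasing order of
#' scar-slice count (seeded tie-breaking) to the fold currently poorest in
#' scar slices.  Warns when any fold's scar fraction deviates more than
#' 10% (relative) from the global fraction.
#'
#' @param dataset a `slice_dataset` (valid slices are counted).
#' @param k number of folds.
#' @param seed integer seed for tie-breaking.
#' @return named integer vector patient_id -> fold (1..k), class
#'   `fold_assignment`, with attribute `table` (per-fold slice counts).
#' @export
make_folds <- function(dataset, k = 10L, seed = 1L) {
  info <- dataset$info[dataset$info$valid, , drop = FALSE]
  pats <- unique(info$patient_id)
  if (length(pats) < k)
    stop(sprintf("only %d patients for %d folds", length(pats), k))
  scar_n <- vapply(pats, function(p) sum(info$label[info$patient_id == p] == 1L),
                   numeric(1L))
  tot_n <- vapply(pats, function(p) sum(info$patient_id == p), numeric(1L))
  set.seed(seed)
  ord <- order(-scar_n, sample.int(length(pats)))
  fold_scar <- numeric(k); fold_tot <- numeric(k); fold_np <- integer(k)
  capacity <- ceiling(length(pats) / k)
  assign <- integer(length(pats))
  for (i in ord) {
    elig <- which(fold_np < capacity)
    j <- elig[order(fold_scar[elig], fold_tot[elig])[1L]]
    assign[i] <- j
    fold_scar[j] <- fold_scar[j] + scar_n[i]
    fold_tot[j] <- fold_tot[j] + tot_n[i]
    fold_np[j] <- fold_np[j] + 1L
  }
  names(assign) <- pats
  glob <- sum(scar_n) / sum(tot_n)
  frac <- ifelse(fold_tot > 0, fold_scar / fold_tot, 0)
  bal <- data.frame(fold = seq_len(k), n_slices = fold_tot,
                    n_scar = fold_scar, scar_fraction = frac)
  if (glob > 0 && any(abs(frac - glob) > 0.1 * glob))
    warning(sprintf("fold scar fractions deviate >10%% from global %.3f: %s",
                    glob, paste(sprintf("%.3f", frac), collapse = ", ")))
  structure(assign, table = bal, global_fraction = glob,
            class = "fold_assignment")
}

#' Patient-wise cross-validation of the CNN
#'
#' For each fold, trains on the other folds and predicts the held-out
#' patients; every valid slice is predicted exactly once out-of-fold.  The
#' pooled predictions are scored as one test set.
#'
#' @param dataset a `slice_dataset`.
#' @param config a [train_config()] (the tuned defaults train 100 epochs
#'   per fold).
#' @param k number of folds (default 10).
#' @param architecture network variant.
#' @param seed master seed (folds and per-fold training).
#' @param n_boot bootstrap resamples for the pooled AUC interval.
#' @return object of class `scar_cv`: `info` (valid slices with
#'   out-of-fold `probability` and `fold`), `report` (an `eval_report`),
#'   `folds`, `config`.
#' @export
cross_validate <- function(dataset, config = train_config(), k = 10L,
                           architecture = "vgg_small", seed = 1L,
                           n_boot = 2000L) {
  folds <- make_folds(dataset, k, seed)
  ds <- valid_samples(dataset)
  info <- ds$info
  info$fold <- as.integer(folds[info$patient_id])
  info$probability <- NA_real_
  models <- vector("list", k)
  for (j in seq_len(k)) {
    tr <- which(info$fold != j)
    te <- which(info$fold == j)
    if (length(te) == 0L) next
    fit <- scar_cnn(ds[tr], config, architecture, seed = seed + j)
    info$probability[te] <- predict(fit, ds[te])
    models[[j]] <- fit
  }
  rep <- eval_report(info$probability, info$label,
                     threshold = config$prediction_threshold,
                     n_boot = n_boot, seed = seed)
  structure(list(info = info, report = rep, folds = folds, config = config,
                 architecture = architecture, models = models, seed = seed),
            class = "scar_cv")
}

#' @export
print.scar_cv <- function(x, ...) {
  k <- length(unique(x$info$fold))
  cat(sprintf("%d-fold patient-wise cross-validation (%s):\n", k,
              x$architecture))
  print(x$report)
  invisible(x)
}

#' @export
plot.scar_cv <- function(x, ...) plot(x$report, ...)

#' Particle swarm configuration
#'
#' Standard global-best PSO constants (inertia 0.729, cognitive = social =
#' 1.49445).  `bounds` rows are hyperparameters, columns lower/upper; the
#' shipped defaults bracket the tuned values (learning rate 0.009,
#' momentum 0.73, batch 10, gamma 1.560, alpha 0.6).
#'
#' @param n_particles swarm size.
#' @param iterations PSO iterations.
#' @param inertia,cognitive,social velocity-update coefficients.
#' @param bounds named list of `c(lower, upper)` per parameter.
#' @param seed integer seed.
#' @return list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 20L, iterations = 30L,
                         inertia = 0.729, cognitive = 1.49445,
                         social = 1.49445,
                         bounds = list(learning_rate = c(1e-4, 0.05),
                                       momentum = c(0.5, 0.99),
                                       batch_size = c(4, 32),
                                       gamma = c(0, 3),
                                       alpha = c(0.1, 1)),
                         seed = 1L) {
  if (any(vapply(bounds, function(b) b[2L] < b[1L], logical(1L))))
    stop("bounds must be ordered (lower <= upper)")
  if (inertia <= 0 || cognitive <= 0 || social <= 0)
    stop("PSO coefficients must be positive")
  structure(list(n_particles = as.integer(n_particles),
                 iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 bounds = bounds, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Global-best particle swarm maximization
#'
#' Standard velocity update with inertia, cognitive and social terms;
#' positions clamped to the bounds.  Deterministic given the seed.
#'
#' @param objective function(named numeric vector) -> scalar to maximize.
#' @param swarm a [swarm_config()] (its `bounds` define the search space).
#' @return list: `par` (best position), `value`, `trace` (best value per
#'   iteration), `evaluations`.
#' @export
pso_optimize <- function(objective, swarm = swarm_config()) {
  if (length(swarm$bounds) == 0L) stop("empty parameter bounds")
  lo <- vapply(swarm$bounds, `[`, numeric(1L), 1L)
  hi <- vapply(swarm$bounds, `[`, numeric(1L), 2L)
  d <- length(lo); np <- swarm$n_particles
  set.seed(swarm$seed)
  X <- matrix(runif(np * d, rep(lo, each = np), rep(hi, each = np)), np, d)
  V <- matrix(runif(np * d, -(rep(hi - lo, each = np)), rep(hi - lo, each = np)),
              np, d) * 0.1
  colnames(X) <- names(swarm$bounds)
  fx <- apply(X, 1L, function(p) objective(stats::setNames(p, names(swarm$bounds))))
  Pb <- X; fpb <- fx
  g <- which.max(fpb)
  trace <- numeric(swarm$iterations)
  evals <- np
  for (it in seq_len(swarm$iterations)) {
    r1 <- matrix(runif(np * d), np, d)
    r2 <- matrix(runif(np * d), np, d)
    V <- swarm$inertia * V +
      swarm$cognitive * r1 * (Pb - X) +
      swarm$social * r2 * (matrix(Pb[g, ], np, d, byrow = TRUE) - X)
    X <- X + V
    X <- pmax(pmin(X, matrix(hi, np, d, byrow = TRUE)),
              matrix(lo, np, d, byrow = TRUE))
    fx <- apply(X, 1L, function(p) objective(stats::setNames(p, names(swarm$bounds))))
    evals <- evals + np
    upd <- fx > fpb
    Pb[upd, ] <- X[upd, ]; fpb[upd] <- fx[upd]
    g <- which.max(fpb)
    trace[it] <- fpb[g]
  }
  list(par = stats::setNames(Pb[g, ], names(swarm$bounds)), value = fpb[g],
       trace = trace, evaluations = evals)
}

#' Tune training hyperparameters with particle swarm optimization
#'
#' Maximizes cross-validated accuracy at a reduced epoch budget over
#' learning rate, momentum, batch size (rounded to an integer), focal
#' gamma and alpha.
#'
#' @param dataset a `slice_dataset`.
#' @param swarm a [swarm_config()].
#' @param k folds for the inner cross-validation.
#' @param epochs reduced epoch budget per evaluation (default 10).
#' @param architecture network variant.
#' @param objective optional replacement objective
#'   `function(train_config) -> scalar`; the default is out-of-fold
#'   accuracy.
#' @return list: `config` (best [train_config()]), `value`, `trace`.
#' @export
tune_hyperparameters <- function(dataset, swarm = swarm_config(), k = 3L,
                                 epochs = 10L, architecture = "vgg_small",
                                 objective = NULL) {
  par_to_config <- function(p) {
    train_config(learning_rate = p[["learning_rate"]],
                 momentum = p[["momentum"]],
                 batch_size = max(1L, as.integer(round(p[["batch_size"]]))),
                 epochs = epochs,
                 loss = focal_loss_params(p[["gamma"]], p[["alpha"]]),
                 seed = swarm$seed)
  }
  if (is.null(objective)) {
    objective_cfg <- function(cfg) {
      cv <- cross_validate(dataset, cfg, k = k, architecture = architecture,
                           seed = swarm$seed, n_boot = 0L)
      cv$report$accuracy
    }
  } else objective_cfg <- objective
  res <- pso_optimize(function(p) objective_cfg(par_to_config(p)), swarm)
  list(config = par_to_config(res$par), value = res$value,
       trace = res$trace, par = res$par)
}

#' Minimum-wall-thickness baseline classifier
#'
#' Classifies a slice as scar when its minimum radial wall thickness (from
#' the polar mask) falls below a threshold chosen to maximize accuracy on
#' the training slices.  Serves as the anatomical-measurement comparison
#' baseline for the CNN.
#'
#' @param dataset a `slice_dataset` (valid slices used).
#' @param train_idx indices (into the valid subset) used to pick the
#'   threshold; all slices by default.
#' @return list of class `thickness_baseline`: `thickness`, `score`
#'   (-thickness, higher = more scar-like), `calls`, `threshold`.
#' @export
thickness_baseline <- function(dataset, train_idx = NULL) {
  ds <- valid_samples(dataset)
  if (nrow(ds$info) == 0L) stop("no valid slices")
  th <- dataset_thickness(ds)
  lab <- ds$info$label
  if (is.null(train_idx)) train_idx <- seq_along(th)
  cand <- sort(unique(th[train_idx]))
  cand <- c(cand, max(cand) + 1)
  best_acc <- -1; best_t <- cand[1L]
  for (t in cand) {
    acc <- mean((th[train_idx] < t) == (lab[train_idx] == 1L))
    if (acc > best_acc) { best_acc <- acc; best_t <- t }
  }
  structure(list(thickness = th, score = -th,
                 calls = as.integer(th < best_t), threshold = best_t,
                 train_accuracy = best_acc, info = ds$info),
            class = "thickness_baseline")
}

#' @export
print.thickness_baseline <- function(x, ...) {
  cat(sprintf("wall-thickness baseline: threshold %.1f mm, training accuracy %.3f\n",
              x$threshold, x$train_accuracy))
  invisible(x)
}
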