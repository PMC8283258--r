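## Reported metrics: accuracy, sensitivity/specificity, ROC/AUC with
## bootstrap confidence intervals, Fleiss' kappa, and apex/mid/base rollup.

#' Classification accuracy
#'
#' Fraction of correct predictions: sum of correct calls over the total
#' number of samples.
#'
#' @param calls binary predictions (0/1 vector).
#' @param labels binary ground truth.
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(calls, labels) {
  if (length(calls) == 0L || length(calls) != length(labels))
    stop("calls and labels must be non-empty and of equal length")
  mean(as.integer(calls) == as.integer(labels))
}

#' Sensitivity and specificity
#'
#' TP/(TP+FN) and TN/(TN+FP).
#'
#' @param calls binary predictions.
#' @param labels binary ground truth containing both classes.
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(calls, labels) {
  labels <- as.integer(labels); calls <- as.integer(calls)
  if (!any(labels == 1L)) stop("no positive labels present")
  if (!any(labels == 0L)) stop("no negative labels present")
  c(sensitivity = mean(calls[labels == 1L] == 1L),
    specificity = mean(calls[labels == 0L] == 0L))
}

#' ROC curve and AUC by threshold sweep
#'
#' The ROC is traced by sweeping the decision threshold over the unique
#' predicted probabilities (ties stepped simultaneously); the AUC is the
#' trapezoidal area under it, which equals the Mann-Whitney two-sample
#' statistic with tie correction.
#'
#' @param probabilities predicted scores.
#' @param labels binary ground truth containing both classes.
#' @return list with `auc` and `roc_points` (data.frame fpr, tpr,
#'   threshold; thresholds decreasing).
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  ord <- order(probabilities, decreasing = TRUE)
  p_sorted <- probabilities[ord]; l_sorted <- labels[ord]
  tp_cum <- cumsum(l_sorted == 1L)
  fp_cum <- cumsum(l_sorted == 0L)
  last_of_tie <- c(p_sorted[-1L] != p_sorted[-length(p_sorted)], TRUE)
  tpr <- c(0, tp_cum[last_of_tie] / np)
  fpr <- c(0, fp_cum[last_of_tie] / nn)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(auc = auc,
       roc_points = data.frame(fpr = fpr, tpr = tpr,
                               threshold = c(Inf, thr)))
}

#' Percentile bootstrap confidence interval for a score statistic
#'
#' Resamples (probability, label) pairs with replacement; resamples that
#' lose one of the two classes are redrawn.  Returns the percentile
#' interval of the statistic over `n_boot` resamples.
#'
#' @param probabilities predicted scores.
#' @param labels binary ground truth.
#' @param statistic function(probabilities, labels) -> scalar.
#' @param n_boot number of resamples (default 2000).
#' @param level confidence level (default 0.95); `band = "sd"` instead
#'   returns mean +/- one standard deviation of the bootstrap distribution.
#' @param band `"percentile"` or `"sd"`.
#' @param seed integer seed.
#' @return numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(probabilities, labels, statistic, n_boot = 2000L,
                         level = 0.95, band = c("percentile", "sd"),
                         seed = 1L) {
  band <- match.arg(band)
  n <- length(probabilities)
  if (n < 10L) stop("need at least 10 samples to bootstrap")
  labels <- as.integer(labels)
  set.seed(seed)
  two_class <- any(labels == 1L) && any(labels == 0L)
  stats <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (!two_class || (any(labels[idx] == 1L) && any(labels[idx] == 0L)))
        break
    }
    stats[b] <- statistic(probabilities[idx], labels[idx])
  }
  if (band == "sd") {
    m <- mean(stats); s <- sd(stats)
    c(low = m - s, high = m + s)
  } else {
    a <- (1 - level) / 2
    q <- unname(quantile(stats, c(a, 1 - a), type = 7))
    c(low = q[1L], high = q[2L])
  }
}

#' Fleiss' kappa for multi-rater binary agreement
#'
#' Chance-corrected agreement for `n` items rated by `r` raters:
#' `kappa = (Pbar - Pe) / (1 - Pe)` where `Pbar` is the mean per-item
#' pairwise agreement and `Pe` the chance agreement from the marginal
#' category proportions.
#'
#' @param ratings complete items x raters matrix of categorical (e.g. 0/1)
#'   ratings, or an items x categories count matrix when
#'   `counts = TRUE`.
#' @param counts whether `ratings` is already a category-count matrix.
#' @return kappa (scalar).
#' @export
fleiss_kappa <- function(ratings, counts = FALSE) {
  if (counts) {
    nij <- as.matrix(ratings)
  } else {
    ratings <- as.matrix(ratings)
    if (any(is.na(ratings))) stop("ratings matrix must be complete")
    if (nrow(ratings) < 2L || ncol(ratings) < 2L)
      stop("need at least 2 items and 2 raters")
    cats <- sort(unique(as.vector(ratings)))
    nij <- vapply(cats, function(k) rowSums(ratings == k),
                  numeric(nrow(ratings)))
    if (is.null(dim(nij))) nij <- matrix(nij, nrow = nrow(ratings))
  }
  r <- sum(nij[1L, ])
  if (any(rowSums(nij) != r)) stop("unequal rater counts per item")
  n <- nrow(nij)
  pj <- colSums(nij) / (n * r)
  pe <- sum(pj^2)
  if (1 - pe < 1e-12)
    stop("all ratings in a single category: chance agreement is 1, kappa undefined")
  pi_ <- (rowSums(nij^2) - r) / (r * (r - 1))
  (mean(pi_) - pe) / (1 - pe)
}

#' Read a long-format reader ratings CSV into an items x raters matrix
#'
#' Expects columns `item_id`, `rater_id`, `call`; every (item, rater) cell
#' must be present exactly once.
#'
#' @param path CSV file.
#' @return items x raters matrix suitable for [fleiss_kappa()].
#' @export
read_ratings_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "rater_id", "call")
  if (!all(need %in% names(x)))
    stop("ratings CSV must have columns item_id, rater_id, call")
  items <- sort(unique(x$item_id)); raters <- sort(unique(x$rater_id))
  m <- matrix(NA_integer_, length(items), length(raters),
              dimnames = list(items, raters))
  m[cbind(match(x$item_id, items), match(x$rater_id, raters))] <-
    as.integer(x$call)
  if (any(is.na(m))) stop("incomplete ratings: missing (item, rater) cells")
  m
}

#' Roll slice-level calls up to apex/mid/base regions
#'
#' Slices are binned by thirds of their normalized axial position (apex
#' < 1/3, mid 1/3-2/3, base > 2/3); a region is positive iff any retained
#' slice inside it is positive.  Regions without retained slices are
#' `NA` (indeterminate).
#'
#' @param calls binary slice calls.
#' @param positions normalized axial positions in \[0, 1\] (apex-offset
#'   adjusted upstream).
#' @return named integer vector `c(apex, mid, base)` with `NA` for empty
#'   regions.
#' @export
region_rollup <- function(calls, positions) {
  stopifnot(length(calls) == length(positions))
  bin <- cut(positions, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
             labels = c("apex", "mid", "base"), right = TRUE)
  out <- vapply(c("apex", "mid", "base"), function(b) {
    i <- bin == b
    if (!any(i)) return(NA_integer_)
    as.integer(any(calls[i] == 1L))
  }, integer(1L))
  out
}

#' Full evaluation report
#'
#' Accuracy at `threshold`, AUC, sensitivity, specificity, and a bootstrap
#' confidence interval for the AUC.
#'
#' @param probabilities predicted probabilities.
#' @param labels binary ground truth.
#' @param threshold decision threshold (calls are `p >= threshold`).
#' @param n_boot bootstrap resamples for the AUC interval (0 to skip).
#' @param seed seed for the bootstrap.
#' @return list of class `eval_report`.
#' @export
eval_report <- function(probabilities, labels, threshold = 0.5,
                        n_boot = 2000L, seed = 1L) {
  labels <- as.integer(labels)
  calls <- as.integer(probabilities >= threshold)
  acc <- accuracy(calls, labels)
  roc <- roc_auc(probabilities, labels)
  ss <- sensitivity_specificity(calls, labels)
  ci <- if (n_boot > 0L)
    bootstrap_ci(probabilities, labels,
                 function(p, l) roc_auc(p, l)$auc,
                 n_boot = n_boot, seed = seed)
  else c(low = NA_real_, high = NA_real_)
  structure(list(accuracy = acc, auc = roc$auc,
                 sensitivity = unname(ss["sensitivity"]),
                 specificity = unname(ss["specificity"]),
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 n_samples = length(labels), n_positive = sum(labels == 1L),
                 threshold = threshold,
                 roc_points = roc$roc_points),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation on %d slices (%d scar):\n", x$n_samples, x$n_positive))
  cat(sprintf("  accuracy    %.3f\n", x$accuracy))
  cat(sprintf("  AUC         %.3f  [%.3f, %.3f] (bootstrap 95%%)\n",
              x$auc, x$ci_low, x$ci_high))
  cat(sprintf("  sensitivity %.3f\n  specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
plot.eval_report <- function(x, ...) {
  plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Write an evaluation report to JSON
#' @param report an `eval_report`.
#' @param path output file; ROC points go to `<path>.roc.csv`.
#' @return `path` invisibly.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  roc <- x$roc_points
  x$roc_points <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  write.csv(roc, paste0(path, ".roc.csv"), row.names = FALSE)
  invisible(path)
}
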