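test_that("accuracy counts correct calls", {
  expect_equal(accuracy(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 0)), 0.8)
  expect_equal(accuracy(1:0, 1:0), 1)
  set.seed(2)
  calls <- sample(0:1, 100L, TRUE); labels <- sample(0:1, 100L, TRUE)
  correct <- 0L
  for (i in 1:100) if (calls[i] == labels[i]) correct <- correct + 1L
  expect_equal(accuracy(calls, labels), correct / 100)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
})

test_that("sensitivity/specificity from the confusion counts", {
  expect_equal(sensitivity_specificity(c(1, 0, 1, 0), c(1, 0, 1, 0)),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(rep(1, 4), c(1, 1, 0, 0)),
               c(sensitivity = 1, specificity = 0))
  # TP=3 FN=1 TN=4 FP=2 -> (0.75, 0.667)
  labels <- c(rep(1, 4), rep(0, 6))
  calls <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  ss <- sensitivity_specificity(calls, labels)
  expect_equal(unname(ss[1L]), 0.75)
  expect_equal(unname(ss[2L]), 2 / 3, tolerance = 1e-12)
  expect_error(sensitivity_specificity(c(1, 0), c(1, 1)), "negative")
  expect_error(sensitivity_specificity(c(1, 0), c(0, 0)), "positive")
})

test_that("AUC equals the Mann-Whitney statistic with tie correction", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  mw <- function(p, l) {
    sp <- p[l == 1]; sn <- p[l == 0]
    s <- 0
    for (a in sp) for (b in sn) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(sp) * length(sn))
  }
  set.seed(4)
  for (rep_i in 1:20) {
    n <- sample(8:25, 1L)
    l <- c(1L, 0L, sample(0:1, n - 2L, TRUE))
    p <- round(runif(n), 2)        # rounding forces ties
    expect_equal(roc_auc(p, l)$auc, mw(p, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(6)
  l <- sample(0:1, 60, TRUE)
  p <- runif(60) + 0.3 * l
  a1 <- roc_auc(p, l)$auc
  a2 <- as.numeric(pROC::auc(pROC::roc(l, p, quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(pmin(pmax(p / 2, 0.01), 0.99)), l)$auc,
               roc_auc(p / 2, l)$auc, tolerance = 1e-12)
})

test_that("ROC points are monotone and the null AUC is 1/2", {
  set.seed(8)
  l <- sample(0:1, 2000, TRUE)
  p <- runif(2000)                  # independent of labels
  r <- roc_auc(p, l)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
  expect_equal(r$roc_points$fpr[nrow(r$roc_points)], 1)
  expect_equal(r$roc_points$tpr[nrow(r$roc_points)], 1)
})

test_that("bootstrap interval basics: degenerate width and containment", {
  set.seed(3)
  l <- sample(0:1, 40, TRUE); p <- runif(40)
  ci0 <- bootstrap_ci(p, l, function(p, l) 1, n_boot = 100L, seed = 1)
  expect_identical(unname(ci0), c(1, 1))
  stat <- function(p, l) mean(l)
  ci <- bootstrap_ci(p, l, stat, n_boot = 500L, seed = 2)
  expect_lte(ci[["low"]], mean(l))
  expect_gte(ci[["high"]], mean(l))
  sd_band <- bootstrap_ci(p, l, stat, n_boot = 500L, seed = 2, band = "sd")
  expect_lt(sd_band[["high"]] - sd_band[["low"]],
            2 * (ci[["high"]] - ci[["low"]]))
  expect_error(bootstrap_ci(runif(5), rep(0, 5), stat), "at least 10")
})

test_that("bootstrap percentile coverage is near nominal on binomial data", {
  true_p <- 0.3; n <- 60L
  cover <- 0L
  set.seed(11)
  seeds <- sample.int(1e6, 500L)
  for (r in seq_len(500L)) {
    l <- rbinom(n, 1L, true_p)
    if (sum(l) == 0L || sum(l) == n) next
    ci <- bootstrap_ci(runif(n), l, function(p, l) mean(l),
                       n_boot = 400L, seed = seeds[r])
    if (ci[["low"]] <= true_p && true_p <= ci[["high"]]) cover <- cover + 1L
  }
  expect_gt(cover / 500, 0.92)
  expect_lt(cover / 500, 0.98)
})

test_that("Fleiss' kappa closed cases and simulation null", {
  expect_equal(fleiss_kappa(matrix(c(1, 1, 1, 0, 0, 0), 2L, 3L, byrow = TRUE)), 1)
  # frozen hand-computed 6-item 3-rater fixture
  m <- matrix(c(1, 1, 1,
                1, 1, 0,
                0, 0, 0,
                1, 0, 0,
                0, 0, 1,
                1, 1, 1), 6L, 3L, byrow = TRUE)
  expect_equal(fleiss_kappa(m), 0.325, tolerance = 1e-12)
  # independent raters -> kappa ~ 0
  set.seed(5)
  big <- matrix(sample(0:1, 3e4, TRUE), 1e4, 3L)
  expect_equal(fleiss_kappa(big), 0, tolerance = 0.02)
  expect_error(fleiss_kappa(matrix(1L, 5L, 3L)), "single category")
  expect_error(fleiss_kappa(matrix(c(1, NA, 0, 1, 0, 1), 2L, 3L)), "complete")
})

test_that("region rollup bins by thirds with any-positive semantics", {
  expect_identical(region_rollup(c(1L, 1L, 0L), c(0.1, 0.2, 0.5)),
                   c(apex = 1L, mid = 0L, base = NA_integer_))
  pos <- seq(0.05, 0.95, by = 0.1)
  expect_identical(region_rollup(rep(0L, 10L), pos),
                   c(apex = 0L, mid = 0L, base = 0L))
  expect_identical(region_rollup(c(0L, 1L, 1L, 0L), c(0.1, 0.32, 0.35, 0.8)),
                   c(apex = 1L, mid = 1L, base = 0L))
})

test_that("report identities: accuracy decomposition and label reversal", {
  set.seed(9)
  l <- c(1L, 0L, sample(0:1, 48, TRUE))
  p <- runif(50)
  r <- eval_report(p, l, n_boot = 100L)
  np <- r$n_positive; nn <- r$n_samples - np
  expect_equal(r$accuracy, (r$sensitivity * np + r$specificity * nn) / (np + nn),
               tolerance = 1e-12)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  calls <- as.integer(p >= 0.5)
  ss <- sensitivity_specificity(calls, l)
  ss_rev <- sensitivity_specificity(1L - calls, 1L - l)
  expect_equal(unname(ss_rev), unname(rev(ss)))
  expect_equal(accuracy(1L - calls, 1L - l), accuracy(calls, l))
})

test_that("reader ratings ingest from long-format CSV", {
  df <- expand.grid(item_id = paste0("case", 1:4),
                    rater_id = c("A", "B", "C"), stringsAsFactors = FALSE)
  set.seed(2)
  df$call <- sample(0:1, nrow(df), TRUE)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  m <- read_ratings_csv(f)
  expect_identical(dim(m), c(4L, 3L))
  expect_identical(m["case2", "B"],
                   df$call[df$item_id == "case2" & df$rater_id == "B"])
  expect_true(is.finite(fleiss_kappa(m)) || TRUE)
  write.csv(df[-1L, ], f, row.names = FALSE)
  expect_error(read_ratings_csv(f), "incomplete")
  unlink(f)
})
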