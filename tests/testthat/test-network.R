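test_that("focal loss closed forms and monotonicity", {
  expect_identical(focal_loss(1, focal_loss_params(2, 0.5)), 0)
  # gamma = 0, alpha = 1 degenerates to binary cross-entropy
  p <- seq(0.001, 1, by = 0.001)
  expect_lt(max(abs(focal_loss(p, focal_loss_params(0, 1), reduce = FALSE) -
                      (-log(p)))), 1e-12)
  # tuned parameters, independent arithmetic evaluation
  expect_equal(focal_loss(0.9, focal_loss_params(1.560, 0.6)),
               0.00174112173854, tolerance = 1e-9)
  # strictly decreasing in p_t for all parameter combinations
  for (g in c(0, 0.5, 1.560, 3)) for (a in c(0.3, 0.6, 1)) {
    l <- focal_loss(p, focal_loss_params(g, a), reduce = FALSE)
    expect_true(all(diff(l) < 0))
  }
  expect_error(focal_loss_params(gamma = -1), "gamma")
  expect_error(focal_loss_params(alpha = 0), "alpha")
})

test_that("network construction: sanity, determinism, parameter ordering", {
  net <- build_network(network_spec("vgg_small"), seed = 4)
  x <- matrix(as.raw(0L), 256^2, 1L)
  p0 <- lvscar:::network_forward(net, x)
  expect_true(is.finite(p0) && p0 > 0 && p0 < 1)
  net2 <- build_network(network_spec("vgg_small"), seed = 4)
  x2 <- matrix(as.raw(sample(0:1, 256^2, TRUE)), 256^2, 1L)
  expect_identical(lvscar:::network_forward(net, x2),
                   lvscar:::network_forward(net2, x2))
  expect_gt(n_parameters(network_spec("vgg16")),
            n_parameters(network_spec("vgg_small")))
  expect_error(network_spec("resnet"))
})

test_that("convolution forward pass matches a direct R implementation", {
  H <- 8L
  spec <- structure(list(architecture = "toy", input_size = H, channels = 1L,
                         layers = list(list(type = "conv", c_in = 1L, c_out = 3L),
                                       list(type = "maxpool"),
                                       list(type = "dense",
                                            n_in = as.integer((H / 2)^2 * 3L),
                                            n_out = 1L, relu = FALSE))),
                    class = "network_spec")
  net <- build_network(spec, seed = 3)
  set.seed(5)
  x <- matrix(sample(0:1, H * H, TRUE), H, H)
  p_cpp <- lvscar:::cnn_predict_cpp(lvscar:::layer_matrix(spec), net$weights,
                                    matrix(as.raw(x), ncol = 1L), H, H, 4L)
  convW <- net$weights[[1L]]; convB <- net$weights[[2L]]
  pad <- matrix(0, H + 2L, H + 2L); pad[2:(H + 1L), 2:(H + 1L)] <- x
  out <- array(0, c(H, H, 3L))
  for (co in 1:3) for (xx in 1:H) for (yy in 1:H) {
    s <- 0
    for (k in 0:8) {
      dx <- k %/% 3L - 1L; dy <- k %% 3L - 1L
      s <- s + pad[yy + 1L + dy, xx + 1L + dx] * convW[k + 1L, co]
    }
    out[yy, xx, co] <- max(0, s + convB[co])
  }
  pool <- array(0, c(H / 2L, H / 2L, 3L))
  for (co in 1:3) for (xx in 1:(H / 2L)) for (yy in 1:(H / 2L))
    pool[yy, xx, co] <- max(out[(2 * yy - 1L):(2 * yy), (2 * xx - 1L):(2 * xx), co])
  feat <- c(pool[, , 1L], pool[, , 2L], pool[, , 3L])
  z <- sum(feat * net$weights[[3L]]) + net$weights[[4L]]
  expect_equal(p_cpp, 1 / (1 + exp(-z)), tolerance = 1e-6)
})

test_that("one SGD epoch on a dense net equals the logistic-regression update", {
  H <- 4L; D <- H * H; n <- 8L
  set.seed(42)
  X <- matrix(as.raw(sample(0:1, D * n, TRUE)), D, n)
  y <- sample(0:1, n, TRUE)
  spec <- tiny_dense_spec(H)
  net <- build_network(spec, seed = 7)
  fit <- lvscar:::cnn_train_cpp(lvscar:::layer_matrix(spec), net$weights,
                                X, H, H, as.integer(y),
                                lr = 0.1, momentum = 0, batch = n, epochs = 1L,
                                gamma = 0, alpha = 1, seed = 1L,
                                augment_shift = FALSE)
  Xd <- matrix(as.integer(X), D, n)
  W <- net$weights[[1L]]; b <- net$weights[[2L]]
  p <- 1 / (1 + exp(-(drop(t(W) %*% Xd) + b)))
  expect_equal(fit$weights[[1L]], W - 0.1 * (Xd %*% matrix((p - y) / n)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$weights[[2L]], b - 0.1 * sum(p - y) / n, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$loss[1L], mean(-log(ifelse(y == 1, p, 1 - p))),
               tolerance = 1e-6)
})

test_that("focal-loss gradient at the output matches numerical differentiation", {
  g <- 1.560; a <- 0.6
  fl_z <- function(z, y) {
    p <- 1 / (1 + exp(-z)); u <- if (y == 1) p else 1 - p
    -a * (1 - u)^g * log(u)
  }
  for (y in c(0L, 1L)) for (z in c(-2, -0.3, 0.4, 1.7)) {
    h <- 1e-6
    num <- (fl_z(z + h, y) - fl_z(z - h, y)) / (2 * h)
    p <- 1 / (1 + exp(-z)); u <- if (y == 1) p else 1 - p
    ana <- -a * (2 * y - 1) * ((1 - u)^(g + 1) - g * u * log(u) * (1 - u)^g)
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("training memorizes a small strongly-separated set", {
  toy <- separable_band_dataset(40L, seed = 2)
  # capacity check: augmentation off so the fixed 40 samples are memorized
  fit <- scar_cnn(toy$masks,
                  train_config(epochs = 30L, seed = 3, augment_shift = FALSE),
                  labels = toy$labels)
  expect_identical(fit$acc_trace[30L], 1)
  p <- predict(fit, toy$masks)
  expect_identical(as.integer(p >= 0.5), toy$labels)
})

test_that("training is deterministic and rejects single-class sets", {
  toy <- toy_band_dataset(20L, seed = 4)
  f1 <- scar_cnn(toy$masks, train_config(epochs = 3L, seed = 5), labels = toy$labels)
  f2 <- scar_cnn(toy$masks, train_config(epochs = 3L, seed = 5), labels = toy$labels)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$weights, f2$weights)
  expect_error(scar_cnn(toy$masks, train_config(epochs = 1L),
                        labels = rep(1L, 20L)), "single class")
})

test_that("default epochs follow the tuned protocol", {
  expect_identical(train_config()$epochs, 100L)
  expect_identical(default_config()$classifier$epochs_final, 500L)
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.009)
  expect_equal(cfg$momentum, 0.73)
  expect_identical(cfg$batch_size, 10L)
  expect_equal(cfg$loss$gamma, 1.560)
  expect_equal(cfg$loss$alpha, 0.6)
})

test_that("predict preserves order, applies the >= threshold rule, checks dims", {
  toy <- toy_band_dataset(30L, seed = 6)
  fit <- scar_cnn(toy$masks, train_config(epochs = 2L), labels = toy$labels)
  p <- predict(fit, toy$masks)
  expect_length(p, 30L)
  perm <- sample(30L)
  # float32 batch composition may perturb the last bits only
  expect_equal(predict(fit, toy$masks[, perm]), p[perm], tolerance = 1e-6)
  # tie at the threshold is a positive call
  expect_identical(as.integer(p >= 0.5),
                   predict(fit, toy$masks, type = "class"))
  fake_half <- fit
  expect_error(predict(fit, toy$masks[1:100, , drop = FALSE]), "input")
})

test_that("positive-class oversampling balances the training set", {
  toy <- separable_band_dataset(40L, seed = 9)
  # force imbalance: keep 5 positives
  keep <- c(which(toy$labels == 1L)[1:5], which(toy$labels == 0L))
  masks <- toy$masks[, keep]; labels <- toy$labels[keep]
  fit <- scar_cnn(masks, train_config(epochs = 1L, oversample_positive = TRUE),
                  labels = labels)
  expect_identical(fit$n_samples, 2L * sum(labels == 0L))
  expect_identical(fit$n_positive, sum(labels == 0L))
  fit0 <- scar_cnn(masks, train_config(epochs = 1L), labels = labels)
  expect_identical(fit0$n_samples, length(labels))
})
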