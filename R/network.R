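## VGG-style network specification, initialization and focal loss.

#' Focal loss parameters
#'
#' @param gamma focusing parameter (>= 0); larger values down-weight easy,
#'   well-classified samples.
#' @param alpha loss weight in (0, 1].
#' @return list of class `focal_loss_params`.  Defaults are the tuned
#'   values gamma = 1.560, alpha = 0.6.
#' @export
focal_loss_params <- function(gamma = 1.560, alpha = 0.6) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(gamma = gamma, alpha = alpha), class = "focal_loss_params")
}

#' Focal loss
#'
#' `FL(p_t) = -alpha * (1 - p_t)^gamma * log(p_t)`, where `p_t` is the
#' probability assigned to the true class.  With `gamma = 0`, `alpha = 1`
#' this is binary cross-entropy.  Probabilities are clamped below at
#' 1e-7 before the logarithm.
#'
#' @param p_true probability of the true class (vectorized).
#' @param params a [focal_loss_params()].
#' @param reduce return the mean over the batch (default) or the
#'   per-sample vector.
#' @return loss value(s).
#' @export
focal_loss <- function(p_true, params = focal_loss_params(), reduce = TRUE) {
  p <- pmin(pmax(p_true, 1e-7), 1)
  l <- -params$alpha * (1 - p)^params$gamma * log(p)
  if (reduce) mean(l) else l
}

#' Network architecture specification
#'
#' `vgg_small` is the desk-scale variant used throughout: a 2x4
#' (radial x angular) average-pool stem (256x256 -> 128x64, keeping full
#' radial wall-thickness detail at the 1 mm scale that carries the scar
#' signal), eight 3x3 convolutions with channel widths
#' (4, 4, 8, 8, 16, 16, 32, 32) and 2x2 max-pooling after each pair, then
#' dense 1024 -> 32 -> 1 with a sigmoid output.  `vgg16` is the
#' full VGG16 convolutional stack (13 convolutions, widths 64..512)
#' adapted to 1-channel 256x256 input with a 4096-4096-1 head.
#'
#' @param architecture `"vgg_small"` or `"vgg16"`.
#' @param input_size input side length in pixels (default 256).
#' @return list of class `network_spec`.
#' @export
network_spec <- function(architecture = c("vgg_small", "vgg16"),
                         input_size = 256L) {
  architecture <- match.arg(architecture)
  conv <- function(ci, co) list(type = "conv", c_in = ci, c_out = co)
  mp <- list(type = "maxpool")
  dense <- function(ni, no, relu) list(type = "dense", n_in = ni, n_out = no,
                                       relu = relu)
  if (architecture == "vgg_small") {
    h <- input_size / 2L / 16L          # radial rows after stem + 4 pools
    w <- input_size / 4L / 16L          # angular cols after stem + 4 pools
    layers <- c(list(list(type = "avgpool", ky = 2L, kx = 4L)),
                list(conv(1L, 4L), conv(4L, 4L), mp,
                     conv(4L, 8L), conv(8L, 8L), mp,
                     conv(8L, 16L), conv(16L, 16L), mp,
                     conv(16L, 32L), conv(32L, 32L), mp),
                list(dense(as.integer(h * w * 32L), 32L, TRUE),
                     dense(32L, 1L, FALSE)))
  } else {
    s <- input_size / 32L
    widths <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                   c(512L, 512L, 512L), c(512L, 512L, 512L))
    layers <- list()
    ci <- 1L
    for (blk in widths) {
      for (co in blk) { layers <- c(layers, list(conv(ci, co))); ci <- co }
      layers <- c(layers, list(mp))
    }
    layers <- c(layers, list(dense(as.integer(s^2 * 512L), 4096L, TRUE),
                             dense(4096L, 4096L, TRUE),
                             dense(4096L, 1L, FALSE)))
  }
  structure(list(architecture = architecture, input_size = as.integer(input_size),
                 channels = 1L, layers = layers),
            class = "network_spec")
}

# integer layer encoding consumed by the C++ engine
layer_matrix <- function(spec) {
  m <- t(vapply(spec$layers, function(l) {
    as.numeric(switch(l$type,
                      avgpool = c(1L, l$ky, l$kx, 0L),
                      conv = c(2L, l$c_in, l$c_out, 0L),
                      maxpool = c(3L, 0L, 0L, 0L),
                      dense = c(4L, l$n_in, l$n_out, as.integer(l$relu))))
  }, numeric(4L)))
  storage.mode(m) <- "integer"
  m
}

#' Number of trainable parameters of a network specification
#' @param spec a [network_spec()] or fitted `scar_cnn`.
#' @return integer parameter count.
#' @export
n_parameters <- function(spec) {
  if (inherits(spec, "scar_cnn") || inherits(spec, "scar_network"))
    spec <- spec$spec
  sum(vapply(spec$layers, function(l) {
    switch(l$type,
           conv = 9 * l$c_in * l$c_out + l$c_out,
           dense = l$n_in * l$n_out + l$n_out,
           0)
  }, numeric(1L)))
}

#' Initialize a network
#'
#' He-normal initialization for convolutional and hidden dense layers,
#' small-variance normal for the output layer; biases start at zero.
#' Reproducible from `seed`.
#'
#' @param spec a [network_spec()] (or architecture name).
#' @param seed integer seed.
#' @return list of class `scar_network` with `spec`, `weights`, `seed`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  if (is.character(spec)) spec <- network_spec(spec)
  set.seed(seed)
  weights <- list()
  nl <- length(spec$layers)
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$type == "conv") {
      fan_in <- 9L * l$c_in
      weights <- c(weights,
                   list(matrix(rnorm(fan_in * l$c_out, 0, sqrt(2 / fan_in)),
                               fan_in, l$c_out),
                        numeric(l$c_out)))
    } else if (l$type == "dense") {
      sdv <- if (i == nl) sqrt(1 / l$n_in) else sqrt(2 / l$n_in)
      weights <- c(weights,
                   list(matrix(rnorm(l$n_in * l$n_out, 0, sdv), l$n_in, l$n_out),
                        numeric(l$n_out)))
    }
  }
  structure(list(spec = spec, weights = weights, seed = as.integer(seed)),
            class = "scar_network")
}

#' @export
print.scar_network <- function(x, ...) {
  cat(sprintf("%s network: %d layers, %s parameters (untrained)\n",
              x$spec$architecture, length(x$spec$layers),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# forward pass of a (possibly untrained) network over a raw mask matrix
network_forward <- function(net, masks, input_size = net$spec$input_size,
                            chunk = 64L) {
  if (net$spec$architecture == "vgg16") chunk <- 2L
  cnn_predict_cpp(layer_matrix(net$spec), net$weights, masks,
                  input_size, input_size, chunk)
}
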