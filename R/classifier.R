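#' The fixed CNN specification
#'
#' The study's binary classifier is architecturally frozen: a convolution
#' layer with 32 3x3 kernels (stride 1, no padding, ReLU), 2x2 max pooling
#' with stride 2, a convolution layer with 64 3x3 kernels (stride 1, no
#' padding, ReLU), 2x2 max pooling with stride 2, a flatten, a fully
#' connected layer with 64 hidden units (ReLU), and a single sigmoid output
#' neuron. Training uses the Adam optimiser on binary cross-entropy for 10
#' epochs. Only the optimisation hyper-parameters below are configurable;
#' every experiment arm must use an identical spec (compare with
#' [model_spec_hash()]).
#'
#' @param epochs training epochs (default 10).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @return a list of class `pcg_model_spec`.
#' @export
model_spec <- function(epochs = 10L, batch_size = 32L, learning_rate = 1e-3) {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0) {
    config_error("invalid model hyper-parameters.")
  }
  structure(
    list(
      architecture = list(
        "conv 32x(3x3) stride 1 valid ReLU", "maxpool 2x2 stride 2",
        "conv 64x(3x3) stride 1 valid ReLU", "maxpool 2x2 stride 2",
        "flatten", "dense 64 ReLU", "dense 1 sigmoid"
      ),
      loss = "binary_cross_entropy", optimizer = "adam",
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate
    ),
    class = "pcg_model_spec"
  )
}

#' @rdname model_spec
#' @param spec a `pcg_model_spec`.
#' @return `model_spec_hash()`: a stable hash of the spec, used to assert
#'   that all arms of an experiment share one model.
#' @export
model_spec_hash <- function(spec) rlang::hash(unclass(spec))

#' Layer-by-layer output shapes
#'
#' Shape arithmetic of the fixed architecture under valid convolutions
#' (\eqn{n - 3 + 1}) and floor 2x2 pooling: for the canonical 100 x 180 x 3
#' input the chain is 98x178x32, 49x89x32, 47x87x64, 23x43x64, a flatten of
#' width 63296, then 64 and 1.
#'
#' @param spec a [model_spec()].
#' @param input_shape integer vector `c(height, width, channels)`.
#' @return a named list of dimension vectors, one per layer.
#' @export
layer_shapes <- function(spec = model_spec(), input_shape = c(100L, 180L, 3L)) {
  h <- input_shape[1]; w <- input_shape[2]
  if (input_shape[3] != 3) config_error("input must have 3 channels.")
  conv1 <- c(h - 2L, w - 2L, 32L)
  if (any(conv1[1:2] < 1)) config_error("input too small for 3x3 convolution.")
  pool1 <- c(conv1[1] %/% 2L, conv1[2] %/% 2L, 32L)
  conv2 <- c(pool1[1] - 2L, pool1[2] - 2L, 64L)
  if (any(conv2[1:2] < 1)) config_error("input too small for the second convolution.")
  pool2 <- c(conv2[1] %/% 2L, conv2[2] %/% 2L, 64L)
  if (any(pool2[1:2] < 1)) config_error("input too small for the second pooling.")
  list(
    conv1 = conv1, pool1 = pool1, conv2 = conv2, pool2 = pool2,
    flatten = prod(pool2), dense = 64L, output = 1L
  )
}

#' @rdname layer_shapes
#' @return `n_parameters()`: the total trainable parameter count.
#' @export
n_parameters <- function(spec = model_spec(), input_shape = c(100L, 180L, 3L)) {
  d <- layer_shapes(spec, input_shape)$flatten
  (32 * 27 + 32) + (64 * 288 + 64) + (64 * d + 64) + (64 + 1)
}

# Stack a list of spectrogram_images (or one H x W x 3 x N array) into the
# [0,1]-scaled double array the C++ kernels consume.
stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) {
    return(images / 255)
  }
  if (!is.list(images) || length(images) == 0) {
    config_error("`images` must be a non-empty list or an H x W x 3 x N array.")
  }
  d <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), d)) config_error("all images must share one shape.")
  }
  arr <- array(0, c(d, length(images)))
  for (i in seq_along(images)) arr[, , , i] <- as.numeric(images[[i]]) / 255
  arr
}

#' Train the fixed CNN
#'
#' Initialises weights from `seed` (He-scaled normal draws), fixes the
#' per-epoch shuffling order from the same seed, and runs exactly
#' `spec$epochs` epochs of minibatch Adam on binary cross-entropy. Training
#' is bit-deterministic: the same seed, images and labels give identical
#' final weights. Pixel intensities are scaled to \eqn{[0, 1]}.
#'
#' @param images list of `spectrogram_image`s (one common shape), or an
#'   `H x W x 3 x N` array already scaled to \eqn{[0, 1]}.
#' @param labels 0/1 vector, one per image; both classes must be present.
#' @param spec a [model_spec()].
#' @param seed integer seed for initialisation and shuffling.
#' @return an object of class `pcg_cnn` with elements `weights`, `spec`,
#'   `input_shape`, `loss_history` (one mean BCE per epoch), `seed`.
#' @export
train_cnn <- function(images, labels, spec = model_spec(), seed = 1L) {
  x <- stack_images(images)
  n <- dim(x)[4]
  labels <- as.numeric(labels)
  if (length(labels) != n) config_error("label / image count mismatch.")
  if (length(unique(labels)) < 2) {
    abort("training set must contain both classes.", class = "pcgaug_degenerate_error")
  }
  shapes <- layer_shapes(spec, dim(x)[1:3])
  d_flat <- shapes$flatten
  weights <- with_seed(seed, list(
    W1 = matrix(rnorm(32 * 27) * sqrt(2 / 27), 32, 27),
    b1 = numeric(32),
    W2 = matrix(rnorm(64 * 288) * sqrt(2 / 288), 64, 288),
    b2 = numeric(64),
    W3 = matrix(rnorm(64 * d_flat) * sqrt(2 / d_flat), 64, d_flat),
    b3 = numeric(64),
    W4 = matrix(rnorm(64) * sqrt(1 / 64), 1, 64),
    b4 = numeric(1)
  ))
  orders <- with_seed(derive_seed(seed, 2), {
    vapply(seq_len(spec$epochs), function(e) sample.int(n), integer(n))
  })
  fit <- .cnn_train_cpp(x, labels, weights, orders,
                        spec$epochs, spec$batch_size, spec$learning_rate,
                        0.9, 0.999, 1e-8)
  loss <- fit$loss_history
  fit$loss_history <- NULL
  structure(
    list(
      weights = fit, spec = spec, input_shape = dim(x)[1:3],
      loss_history = loss, n_train = n,
      class_counts = table(factor(labels, levels = c(0, 1))),
      seed = as.integer(seed)
    ),
    class = "pcg_cnn"
  )
}

#' Predict classification scores
#'
#' Sigmoid outputs of the trained network, one per image, strictly inside
#' \eqn{(0, 1)}.
#'
#' @param model a `pcg_cnn` from [train_cnn()].
#' @param images list of images or an array, as in [train_cnn()].
#' @return a numeric vector of scores.
#' @export
predict_scores <- function(model, images) {
  x <- stack_images(images)
  if (!identical(as.integer(dim(x)[1:3]), as.integer(model$input_shape))) {
    abort("image shape does not match the trained model.", class = "pcgaug_shape_error")
  }
  s <- .cnn_predict_cpp(x, model$weights)
  pmin(1 - 1e-12, pmax(1e-12, s))
}

#' @export
print.pcg_cnn <- function(x, ...) {
  cat(sprintf(
    "<pcg_cnn> trained %d epochs on %d images (%s), final loss %.4f\n",
    length(x$loss_history), x$n_train,
    paste(x$input_shape, collapse = "x"), tail(x$loss_history, 1)
  ))
  invisible(x)
}

#' @export
glance.pcg_cnn <- function(x, ...) {
  tibble(
    n_train = x$n_train, epochs = length(x$loss_history),
    final_loss = tail(x$loss_history, 1),
    n_parameters = n_parameters(x$spec, x$input_shape),
    seed = x$seed
  )
}
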