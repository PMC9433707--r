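#' Convolutional network specification for intelligibility classification
#'
#' The fixed layer stack mapping a rendered feature panel to one of 38
#' intelligibility classes: conv(32, 16x16) -> leakyReLU -> conv(8, 8x8) ->
#' leakyReLU -> maxpool(2x2, stride 2) -> conv(8, 4x4) -> leakyReLU ->
#' maxpool(2x2, stride 1) -> conv(3, 3x3) -> leakyReLU ->
#' maxpool(2x2, stride 1) -> batch norm -> fully-connected(38) -> softmax.
#' Convolutions use same padding (spatial size preserved); the pool strides
#' 2/1/1 are the only setting that reproduces the published output shapes
#' (299 -> 149 -> 148 -> 147).
#'
#' @param n_classes Number of output classes (default 38).
#' @param input_size Input height/width in pixels (default 299).
#' @param filter_scale Integer divisor applied to the conv filter counts
#'   (minimum 1 filter). `filter_scale = 4` with `input_size = 128` is the
#'   reduced profile used for CPU-scale experiments; reported full-scale
#'   numbers always use the default profile.
#' @param leaky_slope Negative slope of the leaky ReLU (default 0.01).
#' @return A `cnn_spec` object: list of layer descriptors plus metadata.
#' @export
cnn_spec <- function(n_classes = 38L, input_size = 299L, filter_scale = 1L,
                     leaky_slope = 0.01) {
  f <- function(n) max(1L, n %/% as.integer(filter_scale))
  layers <- list(
    list(type = "conv", filters = f(32L), kernel = 16L),
    list(type = "leaky_relu", slope = leaky_slope),
    list(type = "conv", filters = f(8L), kernel = 8L),
    list(type = "leaky_relu", slope = leaky_slope),
    list(type = "maxpool", size = 2L, stride = 2L),
    list(type = "conv", filters = f(8L), kernel = 4L),
    list(type = "leaky_relu", slope = leaky_slope),
    list(type = "maxpool", size = 2L, stride = 1L),
    list(type = "conv", filters = f(3L), kernel = 3L),
    list(type = "leaky_relu", slope = leaky_slope),
    list(type = "maxpool", size = 2L, stride = 1L),
    list(type = "batchnorm"),
    list(type = "dense", units = as.integer(n_classes)),
    list(type = "softmax")
  )
  structure(list(layers = layers, n_classes = as.integer(n_classes),
                 input_dim = c(as.integer(input_size), as.integer(input_size), 3L)),
            class = "cnn_spec")
}

#' Layer-by-layer output shapes of a network specification
#'
#' Pure shape arithmetic (same-padding convolutions preserve H and W; a
#' pool of size `p` and stride `s` maps `H` to `floor((H - p) / s) + 1`).
#' Useful for auditing the architecture against its published shape table.
#'
#' @param spec A [cnn_spec()] (or a `csep_cnn` model).
#' @return data.frame with columns `layer`, `out_h`, `out_w`, `out_d`.
#' @export
model_shapes <- function(spec) {
  if (inherits(spec, "csep_cnn")) spec <- spec$spec
  h <- spec$input_dim[1]; w <- spec$input_dim[2]; d <- spec$input_dim[3]
  rows <- data.frame(layer = "input", out_h = h, out_w = w, out_d = d)
  for (L in spec$layers) {
    switch(L$type,
      conv = { d <- L$filters },
      maxpool = {
        h <- (h - L$size) %/% L$stride + 1L
        w <- (w - L$size) %/% L$stride + 1L
      },
      dense = { h <- 1L; w <- 1L; d <- L$units },
      { }   # leaky_relu, batchnorm, softmax: shape-preserving
    )
    rows <- rbind(rows, data.frame(layer = L$type, out_h = h, out_w = w, out_d = d))
  }
  rows
}

#' Build (initialize) the classifier
#'
#' Allocates seeded Glorot-uniform weights for the given specification and
#' verifies, by an actual forward pass of a zero image, that every layer's
#' concrete output tensor matches the shape table of [model_shapes()].
#'
#' @param spec A [cnn_spec()].
#' @param seed Weight-initialization seed.
#' @return A `csep_cnn` model handle (spec + weights + trace).
#' @export
build_model <- function(spec = cnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  weights <- cnn_init_cpp(spec$layers, spec$input_dim, as.integer(seed))
  trace <- cnn_trace_cpp(spec$layers, weights, spec$input_dim)
  expected <- model_shapes(spec)[-1L, c("out_h", "out_w", "out_d")]
  if (!all(trace == as.matrix(expected))) {
    stopf(paste0("layer shape trace does not match the declared shape table:\n",
                 paste(utils::capture.output(print(cbind(expected, trace))),
                       collapse = "\n")))
  }
  structure(list(spec = spec, weights = weights, seed = seed,
                 shape_trace = trace, history = NULL, trained = FALSE),
            class = "csep_cnn")
}

#' @export
print.csep_cnn <- function(x, ...) {
  cat(sprintf("<csep_cnn> input %dx%dx%d, %d classes, %s\n",
              x$spec$input_dim[1], x$spec$input_dim[2], x$spec$input_dim[3],
              x$spec$n_classes,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Actual forward shape trace of a model
#'
#' Runs one zero image through the network and returns each layer's
#' concrete output dimensions.
#'
#' @param model A `csep_cnn` model.
#' @return data.frame with columns `layer`, `out_h`, `out_w`, `out_d`.
#' @export
forward_shape_trace <- function(model) {
  stopifnot(inherits(model, "csep_cnn"))
  tr <- cnn_trace_cpp(model$spec$layers, model$weights, model$spec$input_dim)
  data.frame(layer = vapply(model$spec$layers, `[[`, "", "type"),
             out_h = tr[, 1], out_w = tr[, 2], out_d = tr[, 3])
}

#' Training configuration
#'
#' @param learning_rate Adam initial learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 64).
#' @param epochs Training epochs (default 5).
#' @param validation_fraction Fraction of the training images held out as a
#'   randomly selected validation set (default 0.2).
#' @param shuffle Shuffle training data before each epoch (default TRUE).
#' @param seed RNG seed for shuffling and the validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L, epochs = 5L,
                         validation_fraction = 0.2, shuffle = TRUE, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "train_config")
}

as_image_array <- function(x, input_dim) {
  if (is.list(x) && !is.array(x)) x <- stack_rendered(x)$x
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L || !all(d[1:3] == input_dim)) {
    stopf("images must be %s arrays (got %s)",
          paste(input_dim, collapse = "x"), paste(d, collapse = "x"))
  }
  x
}

#' Train the classifier
#'
#' Minimizes categorical cross-entropy with Adam. A randomly selected
#' `validation_fraction` of the images is held out; the history records
#' per-epoch training and validation loss and accuracy. Fully deterministic
#' for a fixed config seed.
#'
#' @param model A `csep_cnn` from [build_model()].
#' @param x Rendered images: H x W x 3 x N array or list of
#'   `rendered_image`.
#' @param y Integer class indices (0-based, as in [score_label()]).
#' @param config A [train_config()].
#' @return The trained model; `model$history` holds the training history.
#' @export
train_cnn <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "csep_cnn"))
  x <- as_image_array(x, model$spec$input_dim)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stopf("training requires at least 2 distinct classes")
  }
  if (any(y < 0L | y >= model$spec$n_classes)) {
    stopf("class indices must lie in 0..%d", model$spec$n_classes - 1L)
  }
  res <- cnn_train_cpp(x, y, model$spec$layers, model$weights, config)
  model$weights <- res$weights
  model$history <- as.data.frame(res$history)
  model$n_val <- res$n_val
  model$trained <- TRUE
  model
}

#' Class probabilities for rendered images
#'
#' @param model A `csep_cnn`.
#' @param x Images as in [train_cnn()].
#' @param batch_size Forward-pass chunk size (default 64).
#' @return N x n_classes matrix of softmax probabilities (rows sum to 1).
#' @export
predict_cnn <- function(model, x, batch_size = 64L) {
  stopifnot(inherits(model, "csep_cnn"))
  x <- as_image_array(x, model$spec$input_dim)
  cnn_predict_cpp(x, model$spec$layers, model$weights, as.integer(batch_size))
}

#' Classification accuracy on a test set
#'
#' Reports the overall accuracy (correct / total, in percent) and the
#' confusion-matrix form `(TN + TP) / (TN + TP + FN + FP)` micro-averaged
#' over the one-vs-rest confusion matrices of the observed classes.
#'
#' @param model A trained `csep_cnn`.
#' @param x Test images.
#' @param y True 0-based class indices.
#' @return List with `accuracy` (percent), `micro_accuracy` (percent),
#'   `predicted` (0-based indices) and `n`.
#' @export
evaluate_accuracy <- function(model, x, y) {
  y <- as.integer(y)
  if (length(y) == 0L) stopf("empty test set")
  probs <- predict_cnn(model, x)
  pred <- max.col(probs, ties.method = "first") - 1L
  n <- length(y)
  correct <- sum(pred == y)
  k <- length(unique(y))
  tp <- correct
  fp <- n - correct
  fn <- n - correct
  tn <- (k - 1L) * n - fp
  list(accuracy = 100 * correct / n,
       micro_accuracy = 100 * (tn + tp) / (tn + tp + fn + fp),
       predicted = pred, n = n)
}

#' The probabilistic chance level of the classifier
#'
#' @param n_classes Number of classes (default 38).
#' @return Chance accuracy in percent (100 / n_classes; 2.63% for 38).
#' @export
chance_level <- function(n_classes = 38L) 100 / n_classes

#' Save / load a model checkpoint
#'
#' @param model A `csep_cnn`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "csep_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "csep_cnn"))
  model
}
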