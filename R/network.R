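#' Feedforward network model
#'
#' A fully connected feedforward network with logistic activation on every
#' layer (hidden and output). Weights `w[[l]]` have shape
#' `size_l x size_{l-1}` so that `a^(l) = logistic(w^(l) a^(l-1) + b^(l))`.
#'
#' @param layer_sizes integer vector of layer sizes, input first.
#' @param weights list of weight matrices for layers `2..L`.
#' @param biases list of bias vectors for layers `2..L`.
#' @return Object of class `network_model`.
#' @export
network_model <- function(layer_sizes, weights, biases) {
  L <- length(layer_sizes)
  if (L < 2L) stop("a network needs at least input and output layers", call. = FALSE)
  if (length(weights) != L - 1L || length(biases) != L - 1L) {
    stop("need one weight matrix and bias vector per non-input layer", call. = FALSE)
  }
  for (l in seq_len(L - 1L)) {
    w <- weights[[l]]
    if (!is.matrix(w) || nrow(w) != layer_sizes[l + 1] || ncol(w) != layer_sizes[l]) {
      stop(sprintf("weights[[%d]] must be %d x %d", l, layer_sizes[l + 1], layer_sizes[l]),
           call. = FALSE)
    }
    if (length(biases[[l]]) != layer_sizes[l + 1]) {
      stop(sprintf("biases[[%d]] must have length %d", l, layer_sizes[l + 1]),
           call. = FALSE)
    }
    if (any(!is.finite(w)) || any(!is.finite(biases[[l]]))) {
      stop("network parameters must be finite", call. = FALSE)
    }
  }
  structure(list(layer_sizes = as.integer(layer_sizes), weights = weights,
                 biases = lapply(biases, as.numeric)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("Feedforward network (logistic units):",
      paste(x$layer_sizes, collapse = "-"), "\n")
  invisible(x)
}

init_network <- function(layer_sizes, seed = NULL) {
  with_seed(seed, {
    L <- length(layer_sizes)
    weights <- biases <- vector("list", L - 1L)
    for (l in seq_len(L - 1L)) {
      weights[[l]] <- matrix(stats::rnorm(layer_sizes[l + 1] * layer_sizes[l], sd = 0.01),
                             layer_sizes[l + 1], layer_sizes[l])
      biases[[l]] <- rep(0, layer_sizes[l + 1])
    }
    network_model(layer_sizes, weights, biases)
  })
}

#' Parse an architecture string
#'
#' Architecture strings are dash-separated layer sizes such as
#' `"A-500-250-100-1"`; the token `"A"` stands for the input dimension and is
#' replaced by `input_size`.
#'
#' @param string architecture string.
#' @param input_size value substituted for `"A"`.
#' @return Integer vector of layer sizes.
#' @export
parse_architecture <- function(string, input_size) {
  tokens <- strsplit(string, "-", fixed = TRUE)[[1]]
  if (!length(tokens)) stop("empty architecture string", call. = FALSE)
  sizes <- vapply(tokens, function(tok) {
    if (identical(tok, "A")) return(as.integer(input_size))
    if (!grepl("^[0-9]+$", tok)) {
      stop(sprintf("invalid architecture token '%s' in '%s'", tok, string), call. = FALSE)
    }
    as.integer(tok)
  }, integer(1), USE.NAMES = FALSE)
  if (any(sizes <= 0)) stop("layer sizes must be positive in ", string, call. = FALSE)
  sizes
}

#' Forward pass through a network
#'
#' Computes all layer activations for one input vector or a matrix of inputs
#' (rows = samples). All intermediate activations are returned because the
#' backward pass needs them.
#'
#' @param m a [network_model()].
#' @param x input vector of length `layer_sizes[1]`, or an `n x input` matrix.
#' @return List of activation matrices `a[[1..L]]`; `a[[1]]` is the input,
#'   `a[[L]]` the output, each `n x size_l`.
#' @export
feedforward <- function(m, x) {
  a <- vector("list", length(m$layer_sizes))
  a[[1]] <- as_row_matrix(x, m$layer_sizes[1], "input")
  for (l in seq_along(m$weights)) {
    z <- sweep(a[[l]] %*% t(m$weights[[l]]), 2, m$biases[[l]], "+")
    a[[l + 1]] <- logistic(z)
  }
  a
}

network_output <- function(m, x) {
  a <- feedforward(m, x)
  a[[length(a)]]
}

#' Mean squared error of network outputs
#'
#' `E = (1/n) * sum_i || o_i - t_i ||^2` over the `n` output/target pairs.
#'
#' @param outputs numeric matrix (rows = samples) or vector of outputs.
#' @param targets matching matrix/vector of desired outputs.
#' @return Non-negative scalar.
#' @export
mse_error <- function(outputs, targets) {
  outputs <- if (is.null(dim(outputs))) matrix(outputs, ncol = 1) else as.matrix(outputs)
  targets <- if (is.null(dim(targets))) matrix(targets, ncol = 1) else as.matrix(targets)
  if (nrow(outputs) == 0L) stop("mse_error of an empty set is undefined", call. = FALSE)
  if (!all(dim(outputs) == dim(targets))) {
    stop("outputs and targets must have identical shape", call. = FALSE)
  }
  sum((outputs - targets)^2) / nrow(outputs)
}

#' Output encoding for classification networks
#'
#' Binary tasks use either a single output node with hard targets `{0, 1}`
#' (the predicted class is the rounded output) or one node per class with
#' softened one-hot targets `{p, 1-p}` (predicted class = index of the
#' largest output). Three-class tasks use the multi-node form with a
#' `{p, 1-p, 1-p}`-style softened one-hot vector per sample — an extension of
#' the two-node scheme.
#'
#' @param mode `"single"` or `"multi"`.
#' @param p soft target for the true class in multi-node mode, in (0.5, 1].
#' @return Object of class `output_encoding`.
#' @export
output_encoding <- function(mode = c("single", "multi"), p = 0.9) {
  mode <- match.arg(mode)
  stop_if_not_scalar_number(p, "p", lower = 0.5 + 1e-12, upper = 1)
  structure(list(mode = mode, p = p), class = "output_encoding")
}

output_size_for <- function(enc, n_classes) {
  if (enc$mode == "single") {
    if (n_classes != 2L) stop("single-node encoding requires exactly 2 classes", call. = FALSE)
    1L
  } else {
    n_classes
  }
}

encode_targets <- function(labels, enc) {
  labels <- as.factor(labels)
  n_classes <- nlevels(labels)
  if (enc$mode == "single") {
    if (n_classes != 2L) stop("single-node encoding requires exactly 2 classes", call. = FALSE)
    matrix(as.numeric(labels == levels(labels)[2]), ncol = 1)
  } else {
    t_mat <- matrix(1 - enc$p, length(labels), n_classes)
    t_mat[cbind(seq_along(labels), as.integer(labels))] <- enc$p
    t_mat
  }
}

#' Decode network outputs to class indices
#'
#' Single-node encoding rounds the output to 0/1 (class index 1 or 2);
#' multi-node encoding picks the index of the largest output, ties broken by
#' the lowest index.
#'
#' @param output output vector for one sample, or an `n x n_out` matrix.
#' @param enc an [output_encoding()].
#' @return Integer class indices (1-based).
#' @export
predict_class <- function(output, enc) {
  out <- if (is.null(dim(output))) matrix(output, nrow = 1) else as.matrix(output)
  if (enc$mode == "single") {
    if (ncol(out) != 1L) stop("single-node encoding expects one output", call. = FALSE)
    # rounded output; an exact 0.5 goes to the lower class (round-half-to-even)
    as.integer(pmin(pmax(round(out[, 1]), 0), 1)) + 1L
  } else {
    max.col(out, ties.method = "first")
  }
}

#' Initialize a network from a pretrained RBM stack
#'
#' Copies each RBM's weights (transposed into feedforward orientation) and
#' hidden biases into the corresponding hidden layer; the output layer is
#' initialized Normal(0, 0.01) with zero biases. This is the hand-over point
#' between the unsupervised and supervised stages of DBN learning.
#'
#' @param stack list of `rbm` objects with chain-consistent sizes (possibly
#'   empty, which yields a single-layer logistic model).
#' @param input_size input dimension (required when `stack` is empty;
#'   otherwise taken from the first RBM).
#' @param output_size number of output nodes.
#' @param seed seed for the output-layer initialization.
#' @return A [network_model()].
#' @export
init_from_pretrained <- function(stack, output_size, input_size = NULL, seed = NULL) {
  stop_if_not_scalar_number(output_size, "output_size", lower = 1)
  if (length(stack)) {
    input_size <- nrow(stack[[1]]$weights)
    sizes <- c(input_size, vapply(stack, function(m) ncol(m$weights), integer(1)))
    for (r in seq_along(stack)[-1]) {
      if (nrow(stack[[r]]$weights) != sizes[r]) {
        stop(sprintf("stack inconsistent: RBM %d has %d visible units, expected %d",
                     r, nrow(stack[[r]]$weights), sizes[r]), call. = FALSE)
      }
    }
  } else {
    if (is.null(input_size)) stop("input_size required for an empty stack", call. = FALSE)
    sizes <- as.integer(input_size)
  }
  sizes <- c(sizes, as.integer(output_size))
  L <- length(sizes)
  weights <- biases <- vector("list", L - 1L)
  for (r in seq_along(stack)) {
    weights[[r]] <- t(stack[[r]]$weights)
    biases[[r]] <- stack[[r]]$hidden_bias
  }
  with_seed(seed, {
    weights[[L - 1L]] <- matrix(stats::rnorm(sizes[L] * sizes[L - 1L], sd = 0.01),
                                sizes[L], sizes[L - 1L])
    biases[[L - 1L]] <- rep(0, sizes[L])
  })
  network_model(sizes, weights, biases)
}
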