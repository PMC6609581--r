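#' Unfold a pretrained RBM stack into an autoencoder network
#'
#' Builds the mirror-symmetric encoder/decoder network: encoder layers take
#' the RBM weights and hidden biases; decoder layers are initialized with the
#' transposed encoder weights and the RBM visible biases (weights are untied
#' from then on). The central bottleneck is the code layer.
#'
#' @param stack nonempty list of `rbm` objects with chain-consistent sizes.
#' @return A list with `network` (a palindromic [network_model()]) and
#'   `code_layer_index` (position of the code layer in the layer list).
#' @export
build_autoencoder <- function(stack) {
  if (!length(stack)) stop("cannot unfold an empty RBM stack", call. = FALSE)
  sizes <- c(nrow(stack[[1]]$weights),
             vapply(stack, function(m) ncol(m$weights), integer(1)))
  full_sizes <- c(sizes, rev(sizes)[-1])
  c_idx <- length(sizes)  # code layer position
  nl <- length(full_sizes) - 1L
  weights <- biases <- vector("list", nl)
  for (r in seq_along(stack)) {
    weights[[r]] <- t(stack[[r]]$weights)          # encoder: h x v
    biases[[r]] <- stack[[r]]$hidden_bias
  }
  for (r in seq_along(stack)) {
    dec <- nl - r + 1L                             # mirror position
    weights[[dec]] <- stack[[r]]$weights           # decoder: v x h
    biases[[dec]] <- stack[[r]]$visible_bias
  }
  list(network = network_model(full_sizes, weights, biases),
       code_layer_index = c_idx)
}

#' Fit an autoencoder to expression profiles
#'
#' Two-phase autoencoder learning: greedy RBM pretraining of the encoder,
#' unfolding into a mirror-symmetric network ([build_autoencoder()]), then
#' reconstruction fine-tuning with the scaled inputs as their own targets
#' (bprop or rprop via [train_network()]). The code-layer activations are the
#' learned low-dimensional representation, available through [encode()].
#'
#' @param x numeric matrix (samples x genes) or [expression_dataset()].
#' @param hidden integer vector of encoder hidden-layer sizes; the last entry
#'   is the code size.
#' @param control a [train_control()] for reconstruction fine-tuning.
#' @param cd a [cd_control()] for pretraining.
#' @param select_k optional number of top-variance genes to keep.
#' @param seed integer seed overriding the control seeds, as in [dbn()].
#' @return Object of class `autoencoder` with `network`,
#'   `code_layer_index`, `scaler`, `selection`, `history`.
#' @export
autoencoder <- function(x, hidden, control = train_control(), cd = cd_control(),
                        select_k = NULL, seed = NULL) {
  cl <- match.call()
  x <- if (inherits(x, "expression_dataset")) x$expression else as.matrix(x)
  if (!length(hidden)) stop("'hidden' must name at least one encoder layer", call. = FALSE)
  if (!is.null(seed)) {
    cd$seed <- derive_seed(seed, 1)
    control$seed <- derive_seed(seed, 2)
  }
  selection <- NULL
  if (!is.null(select_k)) {
    selection <- select_top_variance(expression_dataset(x), select_k)
    x <- x[, selection$indices, drop = FALSE]
  }
  scaler <- fit_minmax_scaler(x)
  xs <- apply_minmax_scaler(scaler, x)
  stack <- pretrain_rbm_stack(xs, hidden, cd)
  built <- build_autoencoder(stack)
  fit <- train_network(built$network, xs, xs, control, encoding = NULL)
  structure(list(network = fit$model, code_layer_index = built$code_layer_index,
                 scaler = scaler, selection = selection, history = fit$history,
                 hidden = as.integer(hidden), control = control, cd = cd,
                 call = cl),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat("Autoencoder:", paste(x$network$layer_sizes, collapse = "-"),
      sprintf("(code layer %d, size %d)\n", x$code_layer_index,
              x$network$layer_sizes[x$code_layer_index]))
  if (nrow(x$history)) {
    cat(sprintf("  final reconstruction MSE %.5f after %d epochs\n",
                x$history$train_error[nrow(x$history)], nrow(x$history)))
  }
  invisible(x)
}

#' Encode samples into the learned representation
#'
#' For an autoencoder this is the code-layer activation (the forward pass
#' truncated at the bottleneck).
#'
#' @param object a fitted model.
#' @param newdata matrix or [expression_dataset()] in the original gene space.
#' @param ... unused.
#' @return Matrix of `n_samples x code_size` activations.
#' @export
encode <- function(object, newdata, ...) UseMethod("encode")

#' @rdname encode
#' @export
encode.autoencoder <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$expression else as.matrix(newdata)
  if (!is.null(object$selection) && ncol(x) != length(object$scaler$min)) {
    x <- x[, object$selection$indices, drop = FALSE]
  }
  xs <- apply_minmax_scaler(object$scaler, x)
  a <- feedforward(object$network, xs)
  a[[object$code_layer_index]]
}

#' Reconstruct samples through the autoencoder
#'
#' @param object a fitted `autoencoder`.
#' @param newdata matrix or [expression_dataset()].
#' @param ... unused.
#' @return Matrix of reconstructions on the scaled `[0,1]` input scale.
#' @export
predict.autoencoder <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$expression else as.matrix(newdata)
  if (!is.null(object$selection) && ncol(x) != length(object$scaler$min)) {
    x <- x[, object$selection$indices, drop = FALSE]
  }
  network_output(object$network, apply_minmax_scaler(object$scaler, x))
}
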