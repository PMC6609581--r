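#' Contrastive-divergence training options
#'
#' Hyperparameters for CD-k training of a binary-unit RBM. Defaults follow
#' common RBM practice: learning rate 0.1, mini-batches of 10, momentum 0.5
#' switching to 0.9 after 5 epochs, weight-cost 2e-4.
#'
#' @param k number of alternating Gibbs steps per update (CD-k), default 1.
#' @param learning_rate positive step size.
#' @param epochs number of passes over the (shuffled) data.
#' @param batch_size mini-batch size.
#' @param momentum_initial,momentum_final,momentum_switch momentum schedule:
#'   `momentum_initial` up to and including epoch `momentum_switch`, then
#'   `momentum_final`.
#' @param weight_cost L2 weight-cost applied to weights (not biases).
#' @param seed integer seed for initialization and Gibbs sampling.
#' @return A list of class `cd_control`.
#' @export
cd_control <- function(k = 1, learning_rate = 0.1, epochs = 20, batch_size = 10,
                       momentum_initial = 0.5, momentum_final = 0.9,
                       momentum_switch = 5, weight_cost = 2e-4, seed = 1) {
  stop_if_not_scalar_number(k, "k", lower = 1)
  stop_if_not_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("'learning_rate' must be > 0", call. = FALSE)
  stop_if_not_scalar_number(epochs, "epochs", lower = 0)
  stop_if_not_scalar_number(batch_size, "batch_size", lower = 1)
  stop_if_not_scalar_number(momentum_initial, "momentum_initial", 0, 1 - 1e-12)
  stop_if_not_scalar_number(momentum_final, "momentum_final", 0, 1 - 1e-12)
  stop_if_not_scalar_number(weight_cost, "weight_cost", lower = 0)
  structure(list(k = as.integer(k), learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 momentum_initial = momentum_initial,
                 momentum_final = momentum_final,
                 momentum_switch = as.integer(momentum_switch),
                 weight_cost = weight_cost, seed = as.integer(seed)),
            class = "cd_control")
}

new_rbm <- function(weights, visible_bias, hidden_bias) {
  stopifnot(is.matrix(weights),
            length(visible_bias) == nrow(weights),
            length(hidden_bias) == ncol(weights),
            all(is.finite(weights)), all(is.finite(visible_bias)),
            all(is.finite(hidden_bias)))
  structure(list(weights = weights, visible_bias = as.numeric(visible_bias),
                 hidden_bias = as.numeric(hidden_bias)),
            class = "rbm")
}

init_rbm <- function(n_visible, n_hidden, seed = NULL) {
  with_seed(seed, {
    w <- matrix(stats::rnorm(n_visible * n_hidden, sd = 0.01), n_visible, n_hidden)
    new_rbm(w, rep(0, n_visible), rep(0, n_hidden))
  })
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("Binary-unit RBM: %d visible x %d hidden units\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

as_row_matrix <- function(v, n_expected, what) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (ncol(v) != n_expected) {
    stop(sprintf("%s has %d columns, expected %d", what, ncol(v), n_expected),
         call. = FALSE)
  }
  v
}

#' Conditional unit probabilities of an RBM
#'
#' For the binary-unit RBM, `rbm_hidden_probs()` returns
#' P(h_j = 1 | v) = logistic(c_j + sum_i v_i w_ij) and `rbm_visible_probs()`
#' the symmetric P(v_i = 1 | h) = logistic(b_i + sum_j h_j w_ij). Both accept
#' a single vector or a matrix with one configuration per row.
#'
#' @param m an `rbm` model.
#' @param v,h visible / hidden configuration(s) in `[0,1]`.
#' @return Matrix (n x n_hidden or n x n_visible) of probabilities in (0,1);
#'   a vector input yields a 1-row matrix.
#' @export
rbm_hidden_probs <- function(m, v) {
  v <- as_row_matrix(v, nrow(m$weights), "visible input")
  logistic(sweep(v %*% m$weights, 2, m$hidden_bias, "+"))
}

#' @rdname rbm_hidden_probs
#' @export
rbm_visible_probs <- function(m, h) {
  h <- as_row_matrix(h, ncol(m$weights), "hidden input")
  logistic(sweep(h %*% t(m$weights), 2, m$visible_bias, "+"))
}

#' Bernoulli sampling of binary unit states
#'
#' @param p vector or matrix of probabilities in `[0,1]`.
#' @return 0/1 array of the same shape; independent draws from the current
#'   RNG stream.
#' @export
sample_bernoulli <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  out <- (stats::runif(length(p)) < p) * 1
  if (is.matrix(p)) dim(out) <- dim(p)
  out
}

# One CD-k parameter update on a mini-batch.
#
# Positive statistics come from (v0, P(h|v0)); the Gibbs chain samples hidden
# states binary at every step but keeps visible reconstructions as
# probabilities, and the final negative-phase statistics use probabilities on
# both sides (a standard variance-reduction choice). The update mirrors the
# regularized gradient step: delta = momentum * delta_prev
# + lr * (positive - negative)/batch - weight_cost * W, weights only for the
# weight-cost term.

#' Single contrastive-divergence update
#'
#' Applies one CD-k update of the RBM parameters from one mini-batch. Exposed
#' mainly so the update rule can be tested against exact enumeration on tiny
#' machines; [rbm()] drives it in a mini-batch loop.
#'
#' @param m an `rbm` model.
#' @param batch matrix of visible vectors (rows) with entries in `[0,1]`.
#' @param cfg a [cd_control()] list.
#' @param state optional momentum buffers from the previous update (list with
#'   `dw`, `dvb`, `dhb`, `momentum`); `NULL` starts from zero buffers.
#' @return List with updated `model` and `state`.
#' @export
cd_update <- function(m, batch, cfg = cd_control(), state = NULL) {
  batch <- as_row_matrix(batch, nrow(m$weights), "batch")
  if (any(batch < 0 | batch > 1)) stop("batch values must lie in [0,1]", call. = FALSE)
  n <- nrow(batch)
  if (is.null(state)) {
    state <- list(dw = matrix(0, nrow(m$weights), ncol(m$weights)),
                  dvb = rep(0, nrow(m$weights)),
                  dhb = rep(0, ncol(m$weights)),
                  momentum = cfg$momentum_initial)
  }
  h0 <- rbm_hidden_probs(m, batch)
  vk <- batch
  hk <- h0
  for (step in seq_len(cfg$k)) {
    hs <- sample_bernoulli(hk)
    vk <- rbm_visible_probs(m, hs)
    hk <- rbm_hidden_probs(m, vk)
  }
  gw <- (crossprod(batch, h0) - crossprod(vk, hk)) / n
  gvb <- colMeans(batch) - colMeans(vk)
  ghb <- colMeans(h0) - colMeans(hk)
  state$dw <- state$momentum * state$dw + cfg$learning_rate * gw -
    cfg$weight_cost * m$weights
  state$dvb <- state$momentum * state$dvb + cfg$learning_rate * gvb
  state$dhb <- state$momentum * state$dhb + cfg$learning_rate * ghb
  m$weights <- m$weights + state$dw
  m$visible_bias <- m$visible_bias + state$dvb
  m$hidden_bias <- m$hidden_bias + state$dhb
  list(model = m, state = state)
}

#' Train a binary-unit RBM by contrastive divergence
#'
#' Fits a restricted Boltzmann machine to data in `[0,1]` by mini-batch CD-k.
#' Weights are initialized Normal(0, 0.01), biases at zero, and training is a
#' deterministic function of `cfg$seed`.
#'
#' @param data numeric matrix of training vectors (rows) with entries in
#'   `[0,1]`.
#' @param n_hidden number of hidden units.
#' @param cfg a [cd_control()] list.
#' @return A fitted `rbm` object.
#' @export
rbm <- function(data, n_hidden, cfg = cd_control()) {
  data <- as.matrix(data)
  dimnames(data) <- NULL  # keep learned parameters free of dataset dimnames
  if (any(data < 0 | data > 1)) stop("RBM training data must lie in [0,1]", call. = FALSE)
  stop_if_not_scalar_number(n_hidden, "n_hidden", lower = 1)
  set.seed(cfg$seed)
  m <- init_rbm(ncol(data), as.integer(n_hidden))
  state <- NULL
  n <- nrow(data)
  for (epoch in seq_len(cfg$epochs)) {
    momentum <- if (epoch <= cfg$momentum_switch) cfg$momentum_initial else cfg$momentum_final
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      if (!is.null(state)) state$momentum <- momentum
      res <- cd_update(m, data[idx, , drop = FALSE], cfg, state)
      m <- res$model
      state <- res$state
      state$momentum <- momentum
    }
  }
  m
}

#' Greedy layer-wise pretraining of an RBM stack
#'
#' Trains one RBM per requested hidden layer: the first on the input data,
#' each subsequent RBM on the hidden-unit probabilities of the previous one
#' (the previous hidden layer becomes its visible layer). This is the
#' unsupervised pretraining stage of a deep belief network.
#'
#' @param data matrix of training vectors scaled to `[0,1]`.
#' @param hidden_sizes integer vector of hidden layer sizes, bottom to top;
#'   empty yields an empty stack.
#' @param cfg a [cd_control()] list; layer r uses seed `cfg$seed + r - 1`.
#' @return List of fitted `rbm` objects, one per hidden layer.
#' @export
pretrain_rbm_stack <- function(data, hidden_sizes, cfg = cd_control()) {
  data <- as.matrix(data)
  stack <- vector("list", length(hidden_sizes))
  if (!length(hidden_sizes)) return(stack)
  input <- data
  for (r in seq_along(hidden_sizes)) {
    layer_cfg <- cfg
    layer_cfg$seed <- derive_seed(cfg$seed, r - 1)
    stack[[r]] <- rbm(input, hidden_sizes[r], layer_cfg)
    input <- rbm_hidden_probs(stack[[r]], input)
  }
  stack
}
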