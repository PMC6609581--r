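#' Supervised fine-tuning options
#'
#' Hyperparameters for the supervised stage. `algorithm = "bprop"` is
#' mini-batch stochastic gradient descent with momentum and weight-cost;
#' `algorithm = "rprop"` is full-batch iRprop+ (resilient backpropagation
#' with weight backtracking). Momentum follows the schedule 0.5 switching to
#' 0.9 after epoch 50 by default; weight normalization, when enabled,
#' rescales every weight-matrix column to unit L2 norm at the end of each
#' epoch.
#'
#' @param algorithm `"bprop"` or `"rprop"` (iRprop+). Other resilient
#'   variants (`rprop-`, `rprop+`, `irprop-`) are not provided and are
#'   rejected with a clear message.
#' @param learning_rate SGD step size (bprop only).
#' @param weight_cost L2 weight-cost lambda applied to weights, not biases.
#' @param momentum_initial,momentum_final,momentum_switch momentum schedule
#'   (bprop only).
#' @param epochs maximum number of training epochs.
#' @param batch_size mini-batch size (bprop only; rprop is full-batch).
#' @param early_stop_epoch optional hard cutoff: training stops after this
#'   epoch regardless of `epochs`.
#' @param weight_normalization logical; normalize weight-matrix columns to
#'   unit L2 norm after each epoch.
#' @param rprop_eta_plus,rprop_eta_minus,rprop_delta0,rprop_delta_min,rprop_delta_max
#'   iRprop+ step-size constants (standard literature values).
#' @param seed integer seed controlling shuffling.
#' @return A list of class `train_control`.
#' @export
train_control <- function(algorithm = c("rprop", "bprop"), learning_rate = 0.1,
                          weight_cost = 0, momentum_initial = 0.5,
                          momentum_final = 0.9, momentum_switch = 50,
                          epochs = 100, batch_size = 10,
                          early_stop_epoch = NULL, weight_normalization = FALSE,
                          rprop_eta_plus = 1.2, rprop_eta_minus = 0.5,
                          rprop_delta0 = 0.1, rprop_delta_min = 1e-6,
                          rprop_delta_max = 50, seed = 1) {
  if (length(algorithm) == 1L && !algorithm %in% c("rprop", "bprop")) {
    stop(sprintf(paste0("algorithm '%s' is not supported: only 'bprop' and 'rprop' ",
                        "(iRprop+) are provided; the rprop-/rprop+/irprop- variants ",
                        "are not implemented"), algorithm), call. = FALSE)
  }
  algorithm <- match.arg(algorithm)
  stop_if_not_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("'learning_rate' must be > 0", call. = FALSE)
  stop_if_not_scalar_number(weight_cost, "weight_cost", lower = 0)
  stop_if_not_scalar_number(epochs, "epochs", lower = 0)
  stop_if_not_scalar_number(batch_size, "batch_size", lower = 1)
  if (!is.null(early_stop_epoch)) {
    stop_if_not_scalar_number(early_stop_epoch, "early_stop_epoch", lower = 0)
  }
  structure(list(algorithm = algorithm, learning_rate = learning_rate,
                 weight_cost = weight_cost,
                 momentum_initial = momentum_initial,
                 momentum_final = momentum_final,
                 momentum_switch = as.integer(momentum_switch),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_epoch = if (!is.null(early_stop_epoch)) as.integer(early_stop_epoch),
                 weight_normalization = isTRUE(weight_normalization),
                 rprop_eta_plus = rprop_eta_plus, rprop_eta_minus = rprop_eta_minus,
                 rprop_delta0 = rprop_delta0, rprop_delta_min = rprop_delta_min,
                 rprop_delta_max = rprop_delta_max, seed = as.integer(seed)),
            class = "train_control")
}

#' Momentum value at a given epoch
#'
#' @param cfg a [train_control()] (or [cd_control()]) list with
#'   `momentum_initial`, `momentum_final`, `momentum_switch`.
#' @param epoch epoch number (1-based).
#' @return The scheduled momentum: the initial value up to and including the
#'   switch epoch, the final value afterwards.
#' @export
momentum_at_epoch <- function(cfg, epoch) {
  stop_if_not_scalar_number(epoch, "epoch", lower = 1)
  if (epoch <= cfg$momentum_switch) cfg$momentum_initial else cfg$momentum_final
}

#' Backpropagated error gradients
#'
#' Computes the gradients of the squared-error objective for one mini-batch
#' by backpropagation: the output-layer error is
#' `delta^(L) = (a^(L) - t) * phi'(z^(L))`, hidden-layer errors are
#' `delta^(l) = (w^(l+1)' delta^(l+1)) * phi'(z^(l))`, and per-parameter
#' gradients are `dE/dw_ij = a_j^(l-1) delta_i`, `dE/db_i = delta_i`, summed
#' over the mini-batch. The per-sample derivative `(a - t)` corresponds to
#' the objective `0.5 * sum_i ||o_i - t_i||^2`.
#'
#' @param m a [network_model()].
#' @param x input matrix (rows = samples) or single vector.
#' @param targets matching target matrix/vector.
#' @return List of class `gradient_set` with `gw` (list of weight-gradient
#'   matrices), `gb` (list of bias-gradient vectors), and `delta` (per-layer
#'   error matrices).
#' @export
backprop_gradients <- function(m, x, targets) {
  a <- feedforward(m, x)
  L <- length(a)
  targets <- if (is.null(dim(targets))) matrix(targets, nrow = nrow(a[[1]])) else as.matrix(targets)
  if (!all(dim(targets) == dim(a[[L]]))) {
    stop("targets shape does not match the network output", call. = FALSE)
  }
  delta <- vector("list", L)
  delta[[L]] <- (a[[L]] - targets) * logistic_prime_from_activation(a[[L]])
  if (L >= 3L) {
    for (l in (L - 1L):2L) {
      delta[[l]] <- (delta[[l + 1L]] %*% m$weights[[l]]) *
        logistic_prime_from_activation(a[[l]])
    }
  }
  gw <- gb <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    gw[[l]] <- crossprod(delta[[l + 1L]], a[[l]])  # sum over the batch
    gb[[l]] <- colSums(delta[[l + 1L]])
  }
  structure(list(gw = gw, gb = gb, delta = delta[-1]), class = "gradient_set")
}

# the batch objective whose exact gradient backprop_gradients computes;
# used by the rprop error comparison and by the finite-difference oracle
batch_objective <- function(m, x, targets, weight_cost = 0) {
  out <- network_output(m, x)
  targets <- if (is.null(dim(targets))) matrix(targets, nrow = nrow(out)) else as.matrix(targets)
  e <- 0.5 * sum((out - targets)^2)
  if (weight_cost > 0) {
    e <- e + 0.5 * weight_cost * sum(vapply(m$weights, function(w) sum(w^2), numeric(1)))
  }
  e
}

#' One SGD update with momentum and weight-cost
#'
#' Applies the regularized gradient-descent update
#' `theta <- theta - eta * g - lambda * theta + nu * delta_theta_prev`,
#' with the weight-cost term applied to weights only.
#'
#' @param m a [network_model()].
#' @param g a `gradient_set` from [backprop_gradients()].
#' @param learning_rate eta.
#' @param weight_cost lambda.
#' @param momentum nu.
#' @param prev_update update record from the previous step (or `NULL`).
#' @return List with the updated `model` and the applied `update` record.
#' @export
sgd_step <- function(m, g, learning_rate, weight_cost = 0, momentum = 0,
                     prev_update = NULL) {
  nl <- length(m$weights)
  if (is.null(prev_update)) {
    prev_update <- list(dw = lapply(m$weights, function(w) w * 0),
                        db = lapply(m$biases, function(b) b * 0))
  }
  upd <- list(dw = vector("list", nl), db = vector("list", nl))
  for (l in seq_len(nl)) {
    upd$dw[[l]] <- -learning_rate * g$gw[[l]] - weight_cost * m$weights[[l]] +
      momentum * prev_update$dw[[l]]
    upd$db[[l]] <- -learning_rate * g$gb[[l]] + momentum * prev_update$db[[l]]
    m$weights[[l]] <- m$weights[[l]] + upd$dw[[l]]
    m$biases[[l]] <- m$biases[[l]] + upd$db[[l]]
  }
  list(model = m, update = upd)
}

#' iRprop+ state and update
#'
#' `irprop_state()` initializes per-parameter step sizes and buffers;
#' `irprop_step()` applies one iRprop+ update to a flat numeric vector of
#' parameters. Per parameter: if the gradient keeps its sign the step size
#' grows (`* eta_plus`, capped at `delta_max`) and the parameter moves by
#' `-sign(g) * delta`; on a sign flip the step size shrinks (`* eta_minus`,
#' floored at `delta_min`), the previous update is reverted when the error
#' increased (weight backtracking), and the stored gradient is zeroed so the
#' next update takes the neutral branch; with a zero product the parameter
#' moves by `-sign(g) * delta` at an unchanged step size.
#'
#' @param n number of parameters.
#' @param delta0 initial step size.
#' @param eta_plus,eta_minus step-size growth/shrink factors.
#' @param delta_min,delta_max step-size bounds.
#' @param params numeric parameter vector.
#' @param g gradient vector at `params`.
#' @param state an `irprop_state`.
#' @param current_error,previous_error objective values used by the
#'   backtracking rule (the previous error of the first call may be `Inf`).
#' @return `irprop_step()` returns a list with updated `params` and `state`.
#' @export
irprop_state <- function(n, delta0 = 0.1, eta_plus = 1.2, eta_minus = 0.5,
                         delta_min = 1e-6, delta_max = 50) {
  structure(list(delta = rep(delta0, n), g_prev = rep(0, n), dw_prev = rep(0, n),
                 eta_plus = eta_plus, eta_minus = eta_minus,
                 delta_min = delta_min, delta_max = delta_max),
            class = "irprop_state")
}

#' @rdname irprop_state
#' @export
irprop_step <- function(params, g, state, current_error, previous_error) {
  stopifnot(length(params) == length(state$delta), length(g) == length(params))
  s <- sign(g) * sign(state$g_prev)
  grow <- s > 0
  shrink <- s < 0
  state$delta[grow] <- pmin(state$delta[grow] * state$eta_plus, state$delta_max)
  state$delta[shrink] <- pmax(state$delta[shrink] * state$eta_minus, state$delta_min)
  step <- -sign(g) * state$delta
  if (any(shrink)) {
    step[shrink] <- if (current_error > previous_error) -state$dw_prev[shrink] else 0
  }
  g_store <- g
  g_store[shrink] <- 0
  params <- params + step
  state$g_prev <- g_store
  state$dw_prev <- step
  list(params = params, state = state)
}

#' Normalize weight-matrix columns to unit L2 norm
#'
#' Rescales every column of every weight matrix so `||W[, j]||_2 = 1`; zero
#' columns are left unchanged. Biases are untouched. Used as an
#' end-of-epoch regularizer.
#'
#' @param m a [network_model()].
#' @return The normalized model.
#' @export
normalize_weights <- function(m) {
  m$weights <- lapply(m$weights, function(w) {
    norms <- sqrt(colSums(w^2))
    scale <- ifelse(norms > 0, norms, 1)
    sweep(w, 2, scale, "/")
  })
  m
}

# flatten / unflatten network parameters for the rprop path
flatten_params <- function(m) {
  unlist(c(lapply(m$weights, as.numeric), lapply(m$biases, as.numeric)))
}

flatten_grads <- function(g) {
  unlist(c(lapply(g$gw, as.numeric), lapply(g$gb, as.numeric)))
}

unflatten_params <- function(m, theta) {
  pos <- 0L
  for (l in seq_along(m$weights)) {
    n <- length(m$weights[[l]])
    m$weights[[l]][] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  for (l in seq_along(m$biases)) {
    n <- length(m$biases[[l]])
    m$biases[[l]] <- theta[pos + seq_len(n)]
    pos <- pos + n
  }
  m
}

accuracy_from_outputs <- function(out, targets, enc) {
  if (is.null(enc)) return(NA_real_)
  mean(predict_class(out, enc) == predict_class(targets, enc))
}

#' Supervised training loop
#'
#' Fine-tunes a network on encoded targets. With `algorithm = "bprop"` each
#' epoch shuffles the data and applies one [sgd_step()] per mini-batch with
#' the scheduled momentum; with `algorithm = "rprop"` each epoch computes the
#' full-batch gradient (weight-cost folded in as `g + lambda * w`, since a
#' sign-based method has no learning rate for a separate decay term) and
#' applies one [irprop_step()]. Weight normalization, when enabled, runs
#' after each epoch's updates. Training stops at `early_stop_epoch` when set.
#'
#' @param m a [network_model()].
#' @param x input matrix, rows = samples, scaled to `[0,1]`.
#' @param targets encoded target matrix (see [output_encoding()]), or the
#'   inputs themselves for reconstruction training.
#' @param control a [train_control()].
#' @param encoding optional [output_encoding()] used to log training /
#'   monitoring accuracy; `NULL` (e.g. for autoencoders) logs `NA`.
#' @param monitor optional held-out list with elements `x` and `targets`
#'   whose accuracy is logged per epoch.
#' @return List with the trained `model` and `history`, a data frame with one
#'   row per executed epoch (`epoch`, `train_error` as the mean squared error
#'   of Eq.-style `(1/n) sum ||o - t||^2`, `train_acc`, `monitor_acc`).
#' @export
train_network <- function(m, x, targets, control = train_control(),
                          encoding = NULL, monitor = NULL) {
  x <- as_row_matrix(x, m$layer_sizes[1], "input")
  targets <- if (is.null(dim(targets))) matrix(targets, nrow = nrow(x)) else as.matrix(targets)
  if (nrow(targets) != nrow(x)) stop("inputs and targets disagree in sample count", call. = FALSE)
  n_epochs <- control$epochs
  if (!is.null(control$early_stop_epoch)) {
    n_epochs <- min(n_epochs, control$early_stop_epoch)
  }
  history <- data.frame(epoch = integer(0), train_error = numeric(0),
                        train_acc = numeric(0), monitor_acc = numeric(0))
  if (n_epochs == 0L) return(list(model = m, history = history))
  set.seed(control$seed)
  n <- nrow(x)
  prev_update <- NULL
  rprop <- NULL
  prev_error <- Inf
  for (epoch in seq_len(n_epochs)) {
    if (control$algorithm == "bprop") {
      nu <- momentum_at_epoch(control, epoch)
      ord <- sample.int(n)
      starts <- seq(1, n, by = control$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + control$batch_size - 1, n)]
        g <- backprop_gradients(m, x[idx, , drop = FALSE], targets[idx, , drop = FALSE])
        res <- sgd_step(m, g, control$learning_rate, control$weight_cost, nu, prev_update)
        m <- res$model
        prev_update <- res$update
      }
    } else {
      g <- backprop_gradients(m, x, targets)
      if (control$weight_cost > 0) {
        for (l in seq_along(g$gw)) {
          g$gw[[l]] <- g$gw[[l]] + control$weight_cost * m$weights[[l]]
        }
      }
      err <- batch_objective(m, x, targets, control$weight_cost)
      if (is.null(rprop)) {
        rprop <- irprop_state(length(flatten_params(m)),
                              delta0 = control$rprop_delta0,
                              eta_plus = control$rprop_eta_plus,
                              eta_minus = control$rprop_eta_minus,
                              delta_min = control$rprop_delta_min,
                              delta_max = control$rprop_delta_max)
      }
      res <- irprop_step(flatten_params(m), flatten_grads(g), rprop, err, prev_error)
      m <- unflatten_params(m, res$params)
      rprop <- res$state
      prev_error <- err
    }
    if (control$weight_normalization) m <- normalize_weights(m)
    out <- network_output(m, x)
    monitor_acc <- if (!is.null(monitor)) {
      accuracy_from_outputs(network_output(m, monitor$x), monitor$targets, encoding)
    } else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch,
      train_error = mse_error(out, targets),
      train_acc = accuracy_from_outputs(out, targets, encoding),
      monitor_acc = monitor_acc
    ))
  }
  list(model = m, history = history)
}
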