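# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: exact RBM quantities come from brute-force state
# enumeration, network gradients from central finite differences of a
# hand-rolled forward pass.

# all binary configurations of n units, one per row
all_binary_states <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

# unnormalized joint p*(v, h) = exp(b'v + c'h + v'Wh)
rbm_joint_unnorm <- function(m, v, h) {
  exp(sum(m$visible_bias * v) + sum(m$hidden_bias * h) +
        as.numeric(t(v) %*% m$weights %*% h))
}

# exact marginal P(v) over all visible states by full enumeration
rbm_exact_visible_probs <- function(m) {
  vs <- all_binary_states(length(m$visible_bias))
  hs <- all_binary_states(length(m$hidden_bias))
  pstar <- apply(vs, 1, function(v) {
    sum(apply(hs, 1, function(h) rbm_joint_unnorm(m, v, h)))
  })
  list(states = vs, probs = pstar / sum(pstar))
}

rbm_exact_nll <- function(m, data) {
  ex <- rbm_exact_visible_probs(m)
  keys <- apply(ex$states, 1, paste, collapse = "")
  -sum(vapply(seq_len(nrow(data)), function(i) {
    log(ex$probs[match(paste(data[i, ], collapse = ""), keys)])
  }, numeric(1)))
}

# exact model expectation E[v_i h_j] by enumeration
rbm_exact_vh_expectation <- function(m) {
  vs <- all_binary_states(length(m$visible_bias))
  hs <- all_binary_states(length(m$hidden_bias))
  num <- matrix(0, length(m$visible_bias), length(m$hidden_bias))
  z <- 0
  for (i in seq_len(nrow(vs))) {
    for (j in seq_len(nrow(hs))) {
      p <- rbm_joint_unnorm(m, vs[i, ], hs[j, ])
      num <- num + p * (vs[i, ] %o% hs[j, ])
      z <- z + p
    }
  }
  num / z
}

# independent step-by-step forward pass (plain loops over layers)
oracle_forward <- function(net, x) {
  a <- x
  for (l in seq_along(net$weights)) {
    a <- stats::plogis(sweep(a %*% t(net$weights[[l]]), 2, net$biases[[l]], "+"))
  }
  a
}

oracle_batch_error <- function(net, x, targets) {
  0.5 * sum((oracle_forward(net, x) - targets)^2)
}

# central finite differences of the batch objective, parameter by parameter
fd_gradients <- function(net, x, targets, h = 1e-5) {
  gw <- lapply(net$weights, function(w) w * 0)
  gb <- lapply(net$biases, function(b) b * 0)
  for (l in seq_along(net$weights)) {
    for (i in seq_along(net$weights[[l]])) {
      up <- net; up$weights[[l]][i] <- up$weights[[l]][i] + h
      dn <- net; dn$weights[[l]][i] <- dn$weights[[l]][i] - h
      gw[[l]][i] <- (oracle_batch_error(up, x, targets) -
                       oracle_batch_error(dn, x, targets)) / (2 * h)
    }
    for (i in seq_along(net$biases[[l]])) {
      up <- net; up$biases[[l]][i] <- up$biases[[l]][i] + h
      dn <- net; dn$biases[[l]][i] <- dn$biases[[l]][i] - h
      gb[[l]][i] <- (oracle_batch_error(up, x, targets) -
                       oracle_batch_error(dn, x, targets)) / (2 * h)
    }
  }
  list(gw = gw, gb = gb)
}

random_network <- function(sizes, seed, weight_sd = 0.5) {
  set.seed(seed)
  weights <- lapply(seq_along(sizes)[-1], function(l) {
    matrix(stats::rnorm(sizes[l] * sizes[l - 1], sd = weight_sd),
           sizes[l], sizes[l - 1])
  })
  biases <- lapply(sizes[-1], function(s) stats::rnorm(s, sd = 0.2))
  network_model(sizes, weights, biases)
}

# a small labeled dataset with a clear two-class signal
tiny_labeled_dataset <- function(n_per_class = 15, n_genes = 40, delta = 2,
                                 seed = 42) {
  simulate_expression(c(n_per_class, n_per_class), n_genes = n_genes,
                      n_differential = max(1, n_genes %/% 4),
                      effect_size = delta, seed = seed)$dataset
}
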