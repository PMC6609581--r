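test_that("backprop gradients vanish at a perfect fit and match the 1-1 closed form", {
  net <- network_model(c(2, 1), list(matrix(c(20, 20), 1, 2)), list(10))
  x <- matrix(c(1, 1), 1, 2)
  g <- backprop_gradients(net, x, matrix(1, 1, 1))
  expect_equal(unname(g$gw[[1]]), matrix(0, 1, 2), tolerance = 1e-12)

  one <- network_model(c(1, 1), list(matrix(0, 1, 1)), list(0))
  g1 <- backprop_gradients(one, 1, 1)
  # a = 0.5, phi' = 0.25, delta = (0.5 - 1) * 0.25 = -0.125; dE/dw = x * delta
  expect_equal(g1$gw[[1]][1, 1], -0.125)
  expect_equal(g1$gb[[1]][1], -0.125)
})

test_that("backprop gradients agree with central finite differences", {
  for (s in 1:6) {
    sizes <- list(c(5, 4, 3, 2), c(4, 3, 2), c(3, 2), c(5, 2, 2),
                  c(2, 4, 1), c(4, 4, 3, 1))[[s]]
    net <- random_network(sizes, seed = s)
    set.seed(100 + s)
    x <- matrix(runif(4 * sizes[1]), 4, sizes[1])
    targets <- matrix(runif(4 * sizes[length(sizes)]), 4, sizes[length(sizes)])
    g <- backprop_gradients(net, x, targets)
    fd <- fd_gradients(net, x, targets)
    for (l in seq_along(g$gw)) {
      expect_lt(max(abs(g$gw[[l]] - fd$gw[[l]]) / pmax(abs(fd$gw[[l]]), 1e-3)), 1e-6)
      expect_lt(max(abs(g$gb[[l]] - fd$gb[[l]]) / pmax(abs(fd$gb[[l]]), 1e-3)), 1e-6)
    }
  }
})

test_that("the SGD update applies learning rate, decay, and momentum as stated", {
  net <- network_model(c(1, 1), list(matrix(1, 1, 1)), list(0.5))
  g <- structure(list(gw = list(matrix(2, 1, 1)), gb = list(1)),
                 class = "gradient_set")
  plain <- sgd_step(net, g, learning_rate = 0.1)
  expect_equal(plain$model$weights[[1]][1, 1], 1 - 0.2)
  expect_equal(plain$model$biases[[1]][1], 0.5 - 0.1)

  zero_g <- structure(list(gw = list(matrix(0, 1, 1)), gb = list(0)),
                      class = "gradient_set")
  decayed <- sgd_step(net, zero_g, learning_rate = 0.1, weight_cost = 0.1)
  expect_equal(decayed$model$weights[[1]][1, 1], 0.9)  # weights scaled by 1 - lambda
  expect_equal(decayed$model$biases[[1]][1], 0.5)      # biases not decayed

  prev <- list(dw = list(matrix(-0.2, 1, 1)), db = list(0))
  kick <- sgd_step(net, zero_g, learning_rate = 0.1, momentum = 0.5,
                   prev_update = prev)
  expect_equal(kick$model$weights[[1]][1, 1], 1 + 0.5 * (-0.2))
})

test_that("a small SGD step decreases the batch error", {
  for (s in 1:8) {
    net <- random_network(c(4, 3, 2), seed = 20 + s)
    set.seed(40 + s)
    x <- matrix(runif(5 * 4), 5, 4)
    targets <- matrix(runif(5 * 2), 5, 2)
    before <- oracle_batch_error(net, x, targets)
    g <- backprop_gradients(net, x, targets)
    after <- sgd_step(net, g, learning_rate = 1e-3)$model
    expect_lt(oracle_batch_error(after, x, targets), before)
  }
})

test_that("iRprop+ minimizes a 1-D quadratic and backtracks exactly", {
  w <- 0; st <- irprop_state(1); prev_e <- Inf
  for (i in 1:100) {
    e <- (w - 3)^2
    r <- irprop_step(w, 2 * (w - 3), st, e, prev_e)
    w <- r$params; st <- r$state; prev_e <- e
  }
  expect_lt(abs(w - 3), 1e-3)

  # constructed sign flip with error increase restores the value two steps back
  st <- irprop_state(1, delta0 = 0.1)
  r1 <- irprop_step(0, 1, st, current_error = 1, previous_error = Inf)
  w1 <- r1$params                                  # moved by -delta0
  expect_equal(w1, -0.1)
  r2 <- irprop_step(w1, 1, r1$state, current_error = 0.9, previous_error = 1)
  r3 <- irprop_step(r2$params, -1, r2$state, current_error = 2, previous_error = 0.9)
  expect_equal(r3$params, w1, tolerance = 1e-15)   # backtracking restores w1
  expect_equal(r3$state$g_prev, 0)                 # neutral branch armed

  # zero gradient: no move, step size untouched
  st0 <- irprop_state(3)
  r0 <- irprop_step(c(1, 2, 3), c(0, 0, 0), st0, 1, Inf)
  expect_identical(r0$params, c(1, 2, 3))
  expect_identical(r0$state$delta, st0$delta)
})

test_that("weight normalization fixes unit columns and is idempotent", {
  net <- network_model(c(2, 2), list(cbind(c(3, 4), c(0, 0))), list(c(0, 0)))
  n1 <- normalize_weights(net)
  expect_equal(n1$weights[[1]][, 1], c(0.6, 0.8))
  expect_equal(n1$weights[[1]][, 2], c(0, 0))      # zero columns untouched
  expect_equal(normalize_weights(n1), n1)
  rand <- random_network(c(5, 4, 2), seed = 2)
  norms <- sapply(normalize_weights(rand)$weights,
                  function(w) max(abs(sqrt(colSums(w^2)) - 1)))
  expect_lt(max(norms), 1e-12)
})

test_that("the momentum schedule switches after the configured epoch", {
  ctl <- train_control("bprop")
  expect_equal(momentum_at_epoch(ctl, 10), 0.5)
  expect_equal(momentum_at_epoch(ctl, 50), 0.5)
  expect_equal(momentum_at_epoch(ctl, 51), 0.9)
  ctl0 <- train_control("bprop", momentum_switch = 0)
  expect_equal(momentum_at_epoch(ctl0, 1), 0.9)
})

test_that("unsupported resilient variants are rejected clearly", {
  expect_error(train_control("irprop-"), "not supported")
  expect_error(train_control("rprop+"), "not supported")
})

test_that("the training loop respects epochs, early stopping, and seeds", {
  net <- random_network(c(4, 3, 1), seed = 3)
  set.seed(9); x <- matrix(runif(20 * 4), 20, 4)
  y <- matrix(rep(c(0, 1), 10), 20, 1)
  none <- train_network(net, x, y, train_control("rprop", epochs = 0))
  expect_identical(none$model, net)
  expect_equal(nrow(none$history), 0L)

  cut <- train_network(net, x, y,
                       train_control("rprop", epochs = 200, early_stop_epoch = 90))
  expect_equal(nrow(cut$history), 90L)
  expect_equal(cut$history$epoch, 1:90)

  ctl <- train_control("bprop", epochs = 5, seed = 11)
  r1 <- train_network(net, x, y, ctl)
  r2 <- train_network(net, x, y, ctl)
  expect_identical(r1$model, r2$model)
})

test_that("rprop separates two distant Gaussian clouds perfectly", {
  set.seed(17)
  n <- 50
  x <- rbind(matrix(rnorm(n * 2, mean = 0), n, 2),
             matrix(rnorm(n * 2, mean = 6), n, 2))   # 6 sigma apart
  x <- apply(x, 2, function(v) (v - min(v)) / diff(range(v)))
  y <- matrix(rep(c(0, 1), each = n), ncol = 1)
  # sanity: the separability oracle (any linear classifier) scores 100%
  lda_like <- as.integer(rowMeans(x) > 0.5)
  expect_equal(mean(lda_like == y[, 1]), 1)
  net <- dbnexpr:::init_network(c(2, 4, 1), seed = 5)
  fit <- train_network(net, x, y, train_control("rprop", epochs = 200),
                       encoding = output_encoding("single"))
  expect_equal(fit$history$train_acc[200], 1)
})
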