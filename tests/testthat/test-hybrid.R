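test_that("a passthrough hybrid is exactly a plain SVM", {
  sim <- tiny_labeled_dataset(n_per_class = 20, n_genes = 30, seed = 10)
  ext <- representation_extractor("passthrough")
  hyb <- hybrid_classifier(sim, extractor = ext, kernel = "linear", cost = 1)
  plain <- e1071::svm(sim$expression, sim$labels, kernel = "linear", cost = 1,
                      scale = FALSE)
  newx <- simulate_expression(c(10, 10), 30, 7, effect_size = 2,
                              seed = 11)$dataset$expression
  expect_identical(as.character(predict(hyb, newx)),
                   as.character(predict(plain, newx)))
  expect_identical(as.character(predict(hyb, sim$expression)),
                   as.character(predict(plain, sim$expression)))
})

test_that("extraction shapes and trivial values are right", {
  sim <- tiny_labeled_dataset(n_per_class = 12, n_genes = 20, seed = 12)
  fit <- dbn(sim, architecture = "A-8-4-1",
             control = train_control("rprop", epochs = 15),
             cd = cd_control(epochs = 3), seed = 1)
  e2 <- representation_extractor("finetuned-dbn", fit, layer_index = 2)
  feats <- extract_features(e2, sim)
  expect_equal(dim(feats), c(24L, 4L))
  e1 <- representation_extractor("finetuned-dbn", fit)  # default last hidden
  expect_equal(ncol(extract_features(e1, sim)), 4L)
  expect_error(representation_extractor("finetuned-dbn", fit, layer_index = 5),
               "outside")

  # zero-weight network maps all features to 0.5
  zfit <- fit
  zfit$network$weights <- lapply(zfit$network$weights, function(w) w * 0)
  zfit$network$biases <- lapply(zfit$network$biases, function(b) b * 0)
  expect_true(all(extract_features(representation_extractor("finetuned-dbn", zfit, 1),
                                   sim) == 0.5))

  # stack extraction chains hidden probabilities
  es <- representation_extractor("pretrained-stack", fit, layer_index = 1)
  manual <- rbm_hidden_probs(fit$stack[[1]],
                             dbnexpr:::apply_minmax_scaler(fit$scaler,
                                                           sim$expression))
  expect_equal(extract_features(es, sim), manual)
})

test_that("prediction decomposes as SVM applied to extracted features", {
  sim <- tiny_labeled_dataset(n_per_class = 15, n_genes = 25, seed = 13)
  fit <- dbn(sim, architecture = "A-6-1",
             control = train_control("rprop", epochs = 20),
             cd = cd_control(epochs = 3), seed = 2)
  ext <- representation_extractor("finetuned-dbn", fit)
  # high cost so the SVM realizes the separating boundary the DBN found
  hyb <- hybrid_classifier(sim, extractor = ext, cost = 100)
  test <- simulate_expression(c(5, 5), 25, 6, effect_size = 2,
                              seed = 14)$dataset
  expect_identical(as.character(predict(hyb, test)),
                   as.character(predict(hyb$svm,
                                        extract_features(ext, test))))
  # a single sample yields a single label
  expect_length(predict(hyb, test$expression[1, , drop = FALSE]), 1)
  # a separable training fit scores 100% on its own training set
  expect_equal(mean(predict(hyb, sim) == sim$labels), 1)
})

test_that("constant features degrade to a flagged majority-class fallback", {
  x <- matrix(5, 12, 4, dimnames = list(paste0("s", 1:12), paste0("g", 1:4)))
  noise <- matrix(rnorm(48, sd = 1), 12, 4)
  ds <- expression_dataset(x + noise,
                           labels = rep(c("a", "b"), c(8, 4)))
  fitz <- dbn(ds, architecture = "A-3-1",
              control = train_control("rprop", epochs = 1),
              cd = cd_control(epochs = 1), seed = 1)
  fitz$network$weights <- lapply(fitz$network$weights, function(w) w * 0)
  fitz$network$biases <- lapply(fitz$network$biases, function(b) b * 0)
  ext <- representation_extractor("finetuned-dbn", fitz, 1)
  expect_warning(hyb <- hybrid_classifier(ds, extractor = ext), "majority")
  expect_true(hyb$degenerate)
  expect_equal(as.character(unique(predict(hyb, ds))), "a")
})

test_that("single-class training labels are rejected", {
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:4)))
  expect_error(hybrid_classifier(x, factor(rep("a", 5)),
                                 representation_extractor("passthrough")),
               "single class")
})

test_that("test extraction reuses the training scaler (no test leakage)", {
  sim <- tiny_labeled_dataset(n_per_class = 10, n_genes = 15, seed = 15)
  fit <- dbn(sim, architecture = "A-5-1",
             control = train_control("rprop", epochs = 5),
             cd = cd_control(epochs = 2), seed = 3)
  ext <- representation_extractor("finetuned-dbn", fit)
  shifted <- sim$expression + 100  # far outside the training range
  feats <- extract_features(ext, shifted)
  # scaler clamps to the training range, so features must stay finite & in (0,1)
  expect_true(all(is.finite(feats)))
  manual <- dbnexpr:::apply_minmax_scaler(fit$scaler, shifted)
  expect_true(all(manual <= 1))
})

test_that("the SVM grid search returns a best setting by CV accuracy", {
  sim <- tiny_labeled_dataset(n_per_class = 15, n_genes = 10, seed = 16)
  grid <- svm_grid_search(sim$expression, sim$labels, kernel = "linear",
                          costs = c(0.1, 1), k = 3, seed = 1)
  expect_equal(nrow(grid), 2L)
  expect_true(all(diff(grid$accuracy) <= 0))
  expect_s3_class(attr(grid, "best"), "data.frame")
})
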