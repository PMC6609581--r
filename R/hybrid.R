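#' Representation extractors for hybrid classifiers
#'
#' A representation extractor maps samples in the original gene space to the
#' feature space a downstream SVM is trained on: the activations of a chosen
#' hidden layer of a fine-tuned DBN, the chained hidden-unit probabilities of
#' a pretrained RBM stack, the code layer of an autoencoder, or the inputs
#' themselves (`passthrough`).
#'
#' @param source one of `"finetuned-dbn"`, `"pretrained-stack"`,
#'   `"autoencoder"`, `"passthrough"`.
#' @param model the fitted model the representation comes from: a [dbn()]
#'   for `"finetuned-dbn"` and `"pretrained-stack"` (its stored stack and
#'   preprocessing are used), an [autoencoder()] for `"autoencoder"`;
#'   ignored for `"passthrough"`.
#' @param layer_index hidden-layer ordinal (1 = first hidden layer); defaults
#'   to the last hidden layer for DBN sources and the code layer for
#'   autoencoders; ignored for `"passthrough"`.
#' @return Object of class `representation_extractor`.
#' @export
representation_extractor <- function(source = c("finetuned-dbn", "pretrained-stack",
                                                "autoencoder", "passthrough"),
                                     model = NULL, layer_index = NULL) {
  source <- match.arg(source)
  if (source %in% c("finetuned-dbn", "pretrained-stack")) {
    if (!inherits(model, "dbn")) {
      stop(sprintf("source '%s' needs a fitted dbn model", source), call. = FALSE)
    }
    n_hidden_layers <- length(model$network$layer_sizes) - 2L
    if (source == "pretrained-stack") n_hidden_layers <- length(model$stack)
    if (n_hidden_layers < 1L) stop("model has no hidden layers to extract from", call. = FALSE)
    if (is.null(layer_index)) layer_index <- n_hidden_layers
    if (layer_index < 1L || layer_index > n_hidden_layers) {
      stop(sprintf("layer_index %d outside 1..%d", layer_index, n_hidden_layers),
           call. = FALSE)
    }
  } else if (source == "autoencoder") {
    if (!inherits(model, "autoencoder")) {
      stop("source 'autoencoder' needs a fitted autoencoder", call. = FALSE)
    }
    layer_index <- model$code_layer_index
  }
  structure(list(source = source, model = model,
                 layer_index = if (!is.null(layer_index)) as.integer(layer_index)),
            class = "representation_extractor")
}

#' Extract learned features
#'
#' Applies a [representation_extractor()] to samples in the original gene
#' space. Test-set extraction reuses the training-set preprocessing
#' (selection and scaling) stored in the underlying model.
#'
#' @param e a [representation_extractor()].
#' @param x matrix (samples x genes) or [expression_dataset()].
#' @return Feature matrix, one row per sample.
#' @export
extract_features <- function(e, x) {
  stopifnot(inherits(e, "representation_extractor"))
  xm <- if (inherits(x, "expression_dataset")) x$expression else as.matrix(x)
  switch(e$source,
    "passthrough" = xm,
    "finetuned-dbn" = {
      xs <- dbn_preprocess(e$model, xm)
      a <- feedforward(e$model$network, xs)
      a[[e$layer_index + 1L]]
    },
    "pretrained-stack" = {
      xs <- dbn_preprocess(e$model, xm)
      for (r in seq_len(e$layer_index)) {
        xs <- rbm_hidden_probs(e$model$stack[[r]], xs)
      }
      xs
    },
    "autoencoder" = encode(e$model, xm)
  )
}

#' Train a hybrid deep-representation + SVM classifier
#'
#' The combined classifier: a representation extractor (already trained on
#' the training data) maps samples to a learned feature space, and an SVM
#' (LIBSVM via \pkg{e1071}) is fitted on those features. Prediction maps
#' test samples through the same extractor and applies the SVM.
#'
#' @param x training samples (matrix or labeled [expression_dataset()]).
#' @param y training labels; taken from `x` when it is a labeled dataset.
#' @param extractor a [representation_extractor()].
#' @param kernel SVM kernel, `"linear"` or `"radial"`.
#' @param cost SVM cost parameter C.
#' @param gamma RBF width; default `1 / n_features`.
#' @return Object of class `hybrid_classifier` with `extractor`, `svm`,
#'   `levels`, and a `degenerate` flag (majority-class fallback used when the
#'   extracted features are all constant).
#' @export
hybrid_classifier <- function(x, y = NULL, extractor, kernel = c("linear", "radial"),
                              cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  dat <- resolve_xy(x, y)
  if (nlevels(dat$y) < 2L) {
    stop("training labels collapse to a single class", call. = FALSE)
  }
  feats <- extract_features(extractor, dat$x)
  degenerate <- all(col_vars(feats) == 0)
  if (degenerate) {
    warning("extracted features are constant; falling back to the majority class",
            call. = FALSE)
    majority <- names(which.max(table(dat$y)))
    return(structure(list(extractor = extractor, svm = NULL,
                          levels = levels(dat$y), majority = majority,
                          degenerate = TRUE),
                     class = "hybrid_classifier"))
  }
  fit <- e1071::svm(feats, dat$y, kernel = kernel, cost = cost,
                    gamma = gamma %||% (1 / ncol(feats)), scale = FALSE)
  structure(list(extractor = extractor, svm = fit, levels = levels(dat$y),
                 kernel = kernel, cost = cost,
                 gamma = gamma %||% (1 / ncol(feats)), degenerate = FALSE),
            class = "hybrid_classifier",
            train_features = feats, train_labels = dat$y)
}

#' @export
print.hybrid_classifier <- function(x, ...) {
  cat("Hybrid classifier:", x$extractor$source, "representation -> SVM\n")
  if (x$degenerate) {
    cat("  DEGENERATE: constant features, majority-class fallback ('",
        x$majority, "')\n", sep = "")
  } else {
    cat(sprintf("  kernel %s, cost %g, gamma %g, %d support vectors\n",
                x$kernel, x$cost, x$gamma, x$svm$tot.nSV))
  }
  invisible(x)
}

#' Predict method for hybrid classifiers
#'
#' @param object a fitted [hybrid_classifier()].
#' @param newdata matrix or [expression_dataset()] in the original gene
#'   space.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.hybrid_classifier <- function(object, newdata, ...) {
  xm <- if (inherits(newdata, "expression_dataset")) newdata$expression else as.matrix(newdata)
  if (object$degenerate) {
    return(factor(rep(object$majority, nrow(xm)), levels = object$levels))
  }
  feats <- extract_features(object$extractor, xm)
  factor(as.character(stats::predict(object$svm, feats)), levels = object$levels)
}

#' Grid search over SVM hyperparameters
#'
#' Small cross-validated grid-search helper over cost and (for the RBF
#' kernel) gamma, on an already-extracted feature matrix.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param kernel `"linear"` or `"radial"`.
#' @param costs candidate cost values.
#' @param gammas candidate gamma values (radial kernel only).
#' @param k number of CV folds.
#' @param seed integer seed for the fold split.
#' @return Data frame of the grid with mean CV accuracy per setting, sorted
#'   best-first; attribute `"best"` holds the top row.
#' @export
svm_grid_search <- function(x, y, kernel = c("linear", "radial"),
                            costs = c(0.1, 1, 10, 100),
                            gammas = 10^(-4:0), k = 5, seed = 1) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (kernel == "linear") gammas <- 1 / ncol(x)
  grid <- expand.grid(cost = costs, gamma = gammas)
  folds <- kfold_split(nrow(x), k, labels = y, seed = seed)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    accs <- vapply(seq_len(k), function(f) {
      te <- folds$fold == f
      fit <- e1071::svm(x[!te, , drop = FALSE], y[!te], kernel = kernel,
                        cost = grid$cost[i], gamma = grid$gamma[i], scale = FALSE)
      mean(stats::predict(fit, x[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  grid <- grid[order(-grid$accuracy, grid$cost), ]
  attr(grid, "best") <- grid[1, ]
  grid
}
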