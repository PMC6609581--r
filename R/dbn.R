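#' Fit a deep belief network classifier
#'
#' Trains a DBN on gene-expression profiles in two stages: unsupervised
#' pretraining (greedy layer-wise stacking of binary-unit RBMs trained by
#' contrastive divergence) followed by supervised fine-tuning of the unrolled
#' network by backpropagation (`bprop`) or resilient backpropagation
#' (`rprop`, iRprop+). Inputs are min-max scaled per gene to `[0,1]` using
#' parameters learned from the training data; the scaler (and optional
#' top-variance gene selection) is stored in the fitted object and re-applied
#' by `predict()`.
#'
#' @param x numeric matrix (samples x genes) or a labeled
#'   [expression_dataset()].
#' @param y class labels (factor); taken from `x` when it is a labeled
#'   dataset.
#' @param architecture architecture string such as `"A-50-10-1"`; `"A"` is
#'   the input dimension after feature selection. The last token must match
#'   the output size implied by `encoding`.
#' @param control a [train_control()] for the fine-tuning stage.
#' @param cd a [cd_control()] for the pretraining stage.
#' @param encoding an [output_encoding()], or `NULL` to choose automatically
#'   (single output node for 2 classes, one node per class for 3).
#' @param pretrain logical; `FALSE` skips RBM pretraining and starts from a
#'   small random initialization.
#' @param select_k optional number of top-variance genes to keep (computed on
#'   the training data).
#' @param monitor optional held-out labeled [expression_dataset()] (or list
#'   with `x`, `y`) whose accuracy is tracked per epoch.
#' @param seed integer seed; when given it overrides the seeds in `control`
#'   and `cd` with deterministically derived values.
#' @return An object of class `dbn` with components `network`
#'   (the fitted [network_model()]), `stack` (pretrained RBMs), `scaler`,
#'   `selection`, `levels`, `encoding`, `history`, `control`, `cd`, `call`.
#' @seealso [predict.dbn()], [cross_validate()], [hybrid_classifier()]
#' @examples
#' sim <- simulate_expression(c(30, 30), n_genes = 50, n_differential = 10,
#'                            effect_size = 2, seed = 7)
#' fit <- dbn(sim$dataset, architecture = "A-10-1",
#'            control = train_control("rprop", epochs = 30), seed = 7)
#' table(predict(fit, sim$dataset), sim$dataset$labels)
#' @export
dbn <- function(x, y = NULL, architecture = "A-50-10-1",
                control = train_control(), cd = cd_control(),
                encoding = NULL, pretrain = TRUE, select_k = NULL,
                monitor = NULL, seed = NULL) {
  cl <- match.call()
  dat <- resolve_xy(x, y)
  x <- dat$x; y <- dat$y
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (!is.null(seed)) {
    cd$seed <- derive_seed(seed, 1)
    control$seed <- derive_seed(seed, 2)
    init_seed <- derive_seed(seed, 3)
  } else {
    init_seed <- derive_seed(control$seed, 3)
  }
  selection <- NULL
  if (!is.null(select_k)) {
    selection <- select_top_variance(expression_dataset(x), select_k)
    x <- x[, selection$indices, drop = FALSE]
  }
  scaler <- fit_minmax_scaler(x)
  xs <- apply_minmax_scaler(scaler, x)
  if (is.null(encoding)) {
    encoding <- output_encoding(if (nlevels(y) == 2L) "single" else "multi")
  }
  out_size <- output_size_for(encoding, nlevels(y))
  sizes <- parse_architecture(architecture, ncol(xs))
  if (sizes[1] != ncol(xs)) {
    stop(sprintf("architecture input size %d does not match the %d input features",
                 sizes[1], ncol(xs)), call. = FALSE)
  }
  if (sizes[length(sizes)] != out_size) {
    stop(sprintf("architecture output size %d does not match encoding output size %d",
                 sizes[length(sizes)], out_size), call. = FALSE)
  }
  hidden <- sizes[-c(1, length(sizes))]
  if (pretrain && length(hidden)) {
    stack <- pretrain_rbm_stack(xs, hidden, cd)
    net <- init_from_pretrained(stack, out_size, seed = init_seed)
  } else {
    stack <- list()
    net <- init_network(sizes, seed = init_seed)
  }
  monitor_set <- NULL
  if (!is.null(monitor)) {
    mdat <- resolve_xy(monitor, NULL)
    mx <- mdat$x
    if (!is.null(selection)) mx <- mx[, selection$indices, drop = FALSE]
    monitor_set <- list(x = apply_minmax_scaler(scaler, mx),
                        targets = encode_targets(factor(mdat$y, levels = levels(y)),
                                                 encoding))
  }
  fit <- train_network(net, xs, encode_targets(y, encoding), control,
                       encoding = encoding, monitor = monitor_set)
  structure(list(network = fit$model, stack = stack, scaler = scaler,
                 selection = selection, levels = levels(y),
                 encoding = encoding, history = fit$history,
                 architecture = architecture, pretrain = pretrain,
                 control = control, cd = cd, call = cl),
            class = "dbn")
}

# accept (matrix, y) or a labeled expression_dataset
resolve_xy <- function(x, y) {
  if (inherits(x, "expression_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- x$expression
  } else if (is.list(x) && !is.null(x$x)) {
    if (is.null(y)) y <- x$y
    x <- as.matrix(x$x)
  } else {
    x <- as.matrix(x)
  }
  if (is.null(y)) stop("class labels are required", call. = FALSE)
  list(x = x, y = droplevels(as.factor(y)))
}

# shared preprocessing for prediction/extraction from a fitted dbn
dbn_preprocess <- function(object, newdata) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$expression else as.matrix(newdata)
  if (!is.null(object$selection)) {
    if (ncol(x) == length(object$scaler$min)) {
      # already restricted to the selected genes
    } else {
      x <- x[, object$selection$indices, drop = FALSE]
    }
  }
  apply_minmax_scaler(object$scaler, x)
}

#' Predict method for DBN classifiers
#'
#' @param object a fitted [dbn()] model.
#' @param newdata matrix (samples x genes, original gene space) or
#'   [expression_dataset()].
#' @param type `"class"` for predicted labels, `"prob"` for the raw network
#'   outputs.
#' @param ... unused.
#' @return A factor of predicted labels, or the output matrix.
#' @export
predict.dbn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- dbn_preprocess(object, newdata)
  out <- network_output(object$network, xs)
  if (type == "prob") return(out)
  factor(object$levels[predict_class(out, object$encoding)], levels = object$levels)
}

#' @export
print.dbn <- function(x, ...) {
  cat("Deep belief network classifier\n")
  cat("  architecture:", paste(x$network$layer_sizes, collapse = "-"),
      sprintf("(%s)", x$architecture), "\n")
  cat("  fine-tuning:", x$control$algorithm,
      sprintf("(%d epochs run)", nrow(x$history)), "\n")
  cat("  pretraining:", if (length(x$stack)) sprintf("%d stacked RBMs", length(x$stack)) else "none", "\n")
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train error %.4f, train accuracy %.3f\n",
                last$train_error, last$train_acc))
  }
  invisible(x)
}

#' @export
summary.dbn <- function(object, ...) {
  structure(list(object = object), class = "summary.dbn")
}

#' @export
print.summary.dbn <- function(x, ...) {
  print(x$object)
  h <- x$object$history
  if (nrow(h)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(h, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Plot the training history of a fitted network
#'
#' Draws the per-epoch training error and, when available, training and
#' monitoring accuracy.
#'
#' @param x a fitted `dbn` (or `autoencoder`) object with a `history`
#'   component.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dbn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot", call. = FALSE)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_error, type = "l", xlab = "epoch",
                 ylab = "training MSE", ...)
  if (!all(is.na(h$train_acc))) {
    graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                   xlab = "epoch", ylab = "accuracy")
    if (!all(is.na(h$monitor_acc))) {
      graphics::lines(h$epoch, h$monitor_acc, lty = 2)
      graphics::legend("bottomright", c("train", "monitor"), lty = 1:2, bty = "n")
    }
  }
  invisible(x)
}
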