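# Versioned JSON model containers. All numeric payloads are written with
# digits = NA (maximum precision), so parameters round-trip bit-exact.

CONTAINER_VERSION <- "1"

mat_to_list <- function(m) list(dim = dim(m), data = as.numeric(m))
list_to_mat <- function(l) matrix(l$data, l$dim[1], l$dim[2])

serialize_network <- function(net) {
  list(layer_sizes = net$layer_sizes,
       weights = lapply(net$weights, mat_to_list),
       biases = net$biases)
}

deserialize_network <- function(l) {
  network_model(as.integer(l$layer_sizes),
                lapply(l$weights, list_to_mat),
                lapply(l$biases, as.numeric))
}

serialize_rbm <- function(m) {
  list(weights = mat_to_list(m$weights), visible_bias = m$visible_bias,
       hidden_bias = m$hidden_bias)
}

deserialize_rbm <- function(l) {
  new_rbm(list_to_mat(l$weights), as.numeric(l$visible_bias),
          as.numeric(l$hidden_bias))
}

serialize_scaler <- function(s) {
  if (is.null(s)) NULL else list(min = s$min, range = s$range)
}

deserialize_scaler <- function(l) {
  if (is.null(l)) return(NULL)
  structure(list(min = as.numeric(l$min), range = as.numeric(l$range)),
            class = "minmax_scaler")
}

serialize_selection <- function(s) {
  if (is.null(s)) NULL
  else list(indices = s$indices, gene_ids = s$gene_ids,
            criterion = s$criterion, k = s$k)
}

deserialize_selection <- function(l) {
  if (is.null(l)) return(NULL)
  structure(list(indices = as.integer(l$indices),
                 gene_ids = as.character(l$gene_ids),
                 criterion = l$criterion, k = as.integer(l$k)),
            class = "feature_selection")
}

#' Write / read fitted models as versioned JSON containers
#'
#' Supported classes: `rbm`, `network_model`, `dbn`, `autoencoder`, and
#' `hybrid_classifier`. Containers store the architecture, all weights and
#' biases at full double precision, the input scaling parameters and feature
#' selection (so test data are transformed exactly as the training data
#' were), and the output encoding; the round trip is bit-exact. For hybrid
#' classifiers the container stores the extractor, the SVM hyperparameters,
#' and the extracted training features and labels; the SVM itself is refit
#' deterministically from those on load.
#'
#' @param object a fitted model.
#' @param path path for the JSON container file.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored object.
#' @export
write_model <- function(object, path) {
  payload <- if (inherits(object, "rbm")) {
    list(type = "rbm", rbm = serialize_rbm(object))
  } else if (inherits(object, "dbn")) {
    list(type = "dbn",
         network = serialize_network(object$network),
         stack = lapply(object$stack, serialize_rbm),
         scaler = serialize_scaler(object$scaler),
         selection = serialize_selection(object$selection),
         levels = object$levels,
         encoding = list(mode = object$encoding$mode, p = object$encoding$p),
         architecture = object$architecture,
         pretrain = object$pretrain)
  } else if (inherits(object, "autoencoder")) {
    list(type = "autoencoder",
         network = serialize_network(object$network),
         code_layer_index = object$code_layer_index,
         scaler = serialize_scaler(object$scaler),
         selection = serialize_selection(object$selection),
         hidden = object$hidden)
  } else if (inherits(object, "hybrid_classifier")) {
    if (object$degenerate) {
      stop("cannot serialize a degenerate (constant-feature) hybrid classifier",
           call. = FALSE)
    }
    list(type = "hybrid_classifier",
         levels = object$levels, kernel = object$kernel, cost = object$cost,
         gamma = object$gamma,
         train_features = mat_to_list(attr(object, "train_features")),
         train_labels = as.character(attr(object, "train_labels")),
         extractor_source = object$extractor$source)
  } else if (inherits(object, "network_model")) {
    list(type = "network_model", network = serialize_network(object))
  } else {
    stop("unsupported model class: ", paste(class(object), collapse = "/"),
         call. = FALSE)
  }
  payload$container_version <- CONTAINER_VERSION
  # I(17) = 17 significant digits, enough for a bit-exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(as.character(l$container_version), CONTAINER_VERSION)) {
    stop("unsupported container version: ", l$container_version, call. = FALSE)
  }
  switch(l$type,
    "rbm" = deserialize_rbm(l$rbm),
    "network_model" = deserialize_network(l$network),
    "dbn" = structure(list(
      network = deserialize_network(l$network),
      stack = lapply(l$stack, deserialize_rbm),
      scaler = deserialize_scaler(l$scaler),
      selection = deserialize_selection(l$selection),
      levels = as.character(l$levels),
      encoding = output_encoding(l$encoding$mode, l$encoding$p),
      history = data.frame(),
      architecture = l$architecture, pretrain = isTRUE(l$pretrain),
      control = NULL, cd = NULL, call = NULL), class = "dbn"),
    "autoencoder" = structure(list(
      network = deserialize_network(l$network),
      code_layer_index = as.integer(l$code_layer_index),
      scaler = deserialize_scaler(l$scaler),
      selection = deserialize_selection(l$selection),
      history = data.frame(), hidden = as.integer(l$hidden),
      control = NULL, cd = NULL, call = NULL), class = "autoencoder"),
    "hybrid_classifier" = {
      feats <- list_to_mat(l$train_features)
      y <- factor(l$train_labels, levels = l$levels)
      ext <- representation_extractor("passthrough")
      hybrid_classifier(feats, y, ext, kernel = l$kernel, cost = l$cost,
                        gamma = l$gamma)
    },
    stop("unknown container type: ", l$type, call. = FALSE)
  )
}
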