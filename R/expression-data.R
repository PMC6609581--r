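#' Expression dataset container
#'
#' Bundles a samples x genes expression matrix (log2-intensity scale) with
#' sample identifiers, gene identifiers, and optional class labels. This is
#' the container every classifier and the evaluation harness in this package
#' operate on.
#'
#' @param expression numeric matrix, rows = samples, columns = genes.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix rownames.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the matrix colnames.
#' @param labels optional factor (or vector coercible to factor) of class
#'   labels, one per sample; 2 or 3 classes are supported downstream.
#' @return An object of class `expression_dataset`: a list with elements
#'   `expression` (matrix with dimnames set), and `labels` (factor or `NULL`).
#' @examples
#' x <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' ds <- expression_dataset(x, labels = c("a", "b", "a"))
#' ds
#' @export
expression_dataset <- function(expression, sample_ids = rownames(expression),
                               gene_ids = colnames(expression), labels = NULL) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("'expression' must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(expression)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(expression)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(expression)) {
    stop("length(sample_ids) must equal nrow(expression)", call. = FALSE)
  }
  if (length(gene_ids) != ncol(expression)) {
    stop("length(gene_ids) must equal ncol(expression)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(expression))) {
    bad <- which(!is.finite(expression), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at sample '%s', gene '%s'",
                 sample_ids[bad[1]], gene_ids[bad[2]]), call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != nrow(expression)) {
      stop("length(labels) must equal the number of samples", call. = FALSE)
    }
  }
  dimnames(expression) <- list(sample_ids, gene_ids)
  structure(list(expression = expression, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes\n",
              nrow(x$expression), ncol(x$expression)))
  if (is.null(x$labels)) {
    cat("labels: none\n")
  } else {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$expression)

sample_ids <- function(ds) rownames(ds$expression)
gene_ids <- function(ds) colnames(ds$expression)

# Row subset preserving labels; used by undersampling and the CV harness.
subset_samples <- function(ds, idx) {
  expression_dataset(ds$expression[idx, , drop = FALSE],
                     labels = if (!is.null(ds$labels)) ds$labels[idx])
}

subset_genes <- function(ds, idx) {
  expression_dataset(ds$expression[, idx, drop = FALSE], labels = ds$labels)
}

#' Read an expression matrix from delimited text
#'
#' Reads a samples x genes (or genes x samples, e.g. GEO series-matrix style)
#' delimited text file with identifiers in the first row and first column.
#' The result is always oriented samples x genes.
#'
#' @param path path to the delimited text file.
#' @param orientation `"samples-as-rows"` (default) or `"genes-as-rows"`; the
#'   latter is transposed on load.
#' @param delimiter field separator, default tab.
#' @return An [expression_dataset()] with empty labels.
#' @details Missing or non-numeric cells are a load error naming the offending
#'   row and column id; duplicate gene identifiers are an error.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples-as-rows", "genes-as-rows"),
                                   delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE, row.names = 1,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  mat <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | !nzchar(trimws(raw[[j]])))
    if (length(bad)) {
      stop(sprintf("non-numeric or empty cell at row '%s', column '%s' in %s",
                   rownames(raw)[bad[1]], colnames(raw)[j], path), call. = FALSE)
    }
    mat[, j] <- v
  }
  if (orientation == "genes-as-rows") mat <- t(mat)
  expression_dataset(mat)
}

#' Attach class labels to a dataset
#'
#' @param ds an [expression_dataset()].
#' @param label_table either a named character vector (names = sample ids) or
#'   a two-column data frame `sample_id`, `label`.
#' @return The dataset with labels aligned to sample order.
#' @details Every sample must be mapped and the mapped labels must span 2 or 3
#'   classes; anything else is an error.
#' @export
attach_labels <- function(ds, label_table) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.data.frame(label_table)) {
    map <- stats::setNames(as.character(label_table[[2]]),
                           as.character(label_table[[1]]))
  } else {
    map <- stats::setNames(as.character(label_table), names(label_table))
  }
  ids <- sample_ids(ds)
  missing <- setdiff(ids, names(map))
  if (length(missing)) {
    stop("no label for sample(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  labels <- factor(unname(map[ids]))
  if (nlevels(labels) < 2L || nlevels(labels) > 3L) {
    stop(sprintf("need 2 or 3 classes, got %d", nlevels(labels)), call. = FALSE)
  }
  expression_dataset(ds$expression, labels = labels)
}

#' Log2 transform of expression values
#'
#' Replaces every value v by log2(v + 1), the usual move for intensity-scale
#' data (e.g. MAS5-preprocessed arrays) that are not yet on a log scale. The
#' +1 offset keeps zeros finite.
#'
#' @param ds an [expression_dataset()] with non-negative values.
#' @return The transformed dataset.
#' @export
log_transform <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (any(ds$expression < 0)) {
    stop("log_transform requires non-negative values", call. = FALSE)
  }
  expression_dataset(log2(ds$expression + 1), labels = ds$labels)
}

#' Select the genes with the highest variance
#'
#' Unsupervised feature selection: keep the `k` genes with the largest sample
#' variance across all samples. Ties are broken by ascending gene index so the
#' selection is reproducible.
#'
#' @param ds an [expression_dataset()].
#' @param k number of genes to keep; if `k` >= number of genes, all genes are
#'   selected.
#' @return An object of class `feature_selection`: list with `indices`
#'   (ordered descending by variance), `gene_ids`, `criterion = "variance"`,
#'   and `k`.
#' @export
select_top_variance <- function(ds, k) {
  stopifnot(inherits(ds, "expression_dataset"))
  stop_if_not_scalar_number(k, "k", lower = 1)
  v <- col_vars(ds$expression)
  k <- min(as.integer(k), length(v))
  ord <- order(-v, seq_along(v))  # descending variance, ties by ascending index
  idx <- ord[seq_len(k)]
  structure(list(indices = idx, gene_ids = gene_ids(ds)[idx],
                 criterion = "variance", k = k),
            class = "feature_selection")
}

#' Balance classes by undersampling
#'
#' Randomly draws, without replacement, `n_min` samples from every class,
#' where `n_min` is the size of the smallest class. The smallest class is kept
#' in full and the original sample order is preserved within the retained set.
#' With three classes every class is reduced to the global minimum count.
#'
#' @param ds a labeled [expression_dataset()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return The balanced dataset.
#' @export
undersample <- function(ds, seed = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$labels) || nlevels(ds$labels) < 2L) {
    stop("undersample needs a labeled dataset with >= 2 classes", call. = FALSE)
  }
  counts <- table(ds$labels)
  n_min <- min(counts)
  with_seed(seed, {
    keep <- integer(0)
    for (cl in levels(ds$labels)) {
      members <- which(ds$labels == cl)
      if (length(members) > n_min) members <- sort(sample(members, n_min))
      keep <- c(keep, members)
    }
    subset_samples(ds, sort(keep))
  })
}

#' k-fold assignment
#'
#' Partitions `1..n` into `k` disjoint folds whose sizes differ by at most
#' one. When `labels` are supplied the split is stratified: each class is
#' dealt cyclically across folds so per-class proportions are preserved as
#' closely as integer counts allow, while overall fold sizes stay balanced.
#'
#' @param n number of samples.
#' @param k number of folds, `2 <= k <= n`.
#' @param labels optional class labels of length `n` for stratification.
#' @param seed integer seed for the random shuffle.
#' @return Object of class `fold_assignment`: list with `fold` (integer in
#'   `1..k` per sample) and `k`.
#' @export
kfold_split <- function(n, k, labels = NULL, seed = NULL) {
  stop_if_not_scalar_number(n, "n", lower = 1)
  stop_if_not_scalar_number(k, "k", lower = 2)
  n <- as.integer(n); k <- as.integer(k)
  if (k > n) stop(sprintf("k = %d folds but only n = %d samples", k, n), call. = FALSE)
  if (!is.null(labels) && length(labels) != n) {
    stop("length(labels) must equal n", call. = FALSE)
  }
  fold <- integer(n)
  with_seed(seed, {
    if (is.null(labels)) {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    } else {
      labels <- as.factor(labels)
      # Continue the fold counter across classes so overall sizes stay within 1.
      cursor <- 0L
      for (cl in sample(levels(labels))) {
        members <- which(labels == cl)
        members <- members[sample.int(length(members))]
        fold[members] <- (cursor + seq_along(members) - 1L) %% k + 1L
        cursor <- cursor + length(members)
      }
    }
  })
  structure(list(fold = fold, k = k), class = "fold_assignment")
}

# ---- min-max scaling to [0, 1] -------------------------------------------
# Binary-unit RBMs expect inputs in [0,1]; expression values are min-max
# scaled per gene with parameters learned on training data only. Test data
# are transformed with the training parameters and clamped into [0,1].

fit_minmax_scaler <- function(x) {
  lo <- unname(apply(x, 2, min))
  hi <- unname(apply(x, 2, max))
  structure(list(min = lo, range = hi - lo), class = "minmax_scaler")
}

apply_minmax_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"), ncol(x) == length(scaler$min))
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  # constant genes carry no information; pin them at 0
  if (any(scaler$range == 0)) out[, scaler$range == 0] <- 0
  out
}

# ---- dataset serialization ------------------------------------------------

#' Write / read an expression dataset as delimited text
#'
#' `write_expression_dataset()` writes `<prefix>_expression.tsv` (samples as
#' rows, full `%.17g` precision so values round-trip bit-exact) and, when
#' labels are present, `<prefix>_labels.tsv` (`sample_id<TAB>label`).
#' `read_expression_dataset()` reads the pair back.
#'
#' @param ds an [expression_dataset()].
#' @param prefix file path prefix for the pair of TSV files.
#' @return `write_expression_dataset()` returns the written paths invisibly;
#'   `read_expression_dataset()` returns the dataset.
#' @export
write_expression_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "expression_dataset"))
  expr_path <- paste0(prefix, "_expression.tsv")
  x <- ds$expression
  lines <- c(paste(c("sample_id", gene_ids(ds)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(sample_ids(ds)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, expr_path)
  paths <- expr_path
  if (!is.null(ds$labels)) {
    lab_path <- paste0(prefix, "_labels.tsv")
    writeLines(c("sample_id\tlabel",
                 paste(sample_ids(ds), as.character(ds$labels), sep = "\t")),
               lab_path)
    paths <- c(paths, lab_path)
  }
  invisible(paths)
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(prefix) {
  ds <- read_expression_matrix(paste0(prefix, "_expression.tsv"))
  lab_path <- paste0(prefix, "_labels.tsv")
  if (file.exists(lab_path)) {
    tab <- utils::read.table(lab_path, sep = "\t", header = TRUE,
                             colClasses = "character")
    ds <- attach_labels(ds, tab)
  }
  ds
}
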