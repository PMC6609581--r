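#' Confusion counts for a binary task
#'
#' @param predicted predicted labels.
#' @param truth true labels of the same length.
#' @param positive the label counted as positive.
#' @return List of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth, positive) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (!length(truth)) stop("cannot build a confusion table from no samples", call. = FALSE)
  p <- as.character(predicted) == as.character(positive)
  t <- as.character(truth) == as.character(positive)
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+FN+TN)`, sensitivity (true positive rate)
#' `TP/(TP+FN)`, specificity (true negative rate) `TN/(TN+FP)`, and error
#' rate `(FP+FN)/total`. A metric with a zero denominator is reported as
#' `NA` (undefined), never as 0. Accuracy and error rate always sum to 1.
#'
#' @param counts a [confusion_counts()] object.
#' @return Named list with `accuracy`, `tpr`, `tnr`, `error_rate`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("empty confusion table", call. = FALSE)
  list(
    accuracy = (counts$tp + counts$tn) / total,
    tpr = if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_,
    tnr = if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp) else NA_real_,
    error_rate = (counts$fp + counts$fn) / total
  )
}

# ---- learner specifications ----------------------------------------------
# A cv_learner bundles a fit(ds_train, seed) and a predict(fit, ds_test)
# closure plus the feature-selection size the harness may hoist to global
# scope. Constructors cover the classifier families studied here.

new_learner <- function(name, fit, predict, select_k = NULL) {
  structure(list(name = name, fit = fit, predict = predict, select_k = select_k),
            class = "cv_learner")
}

#' @export
print.cv_learner <- function(x, ...) {
  cat("cv_learner:", x$name, "\n")
  invisible(x)
}

#' Learner specifications for the cross-validation harness
#'
#' Each constructor returns a self-contained learner (fit + predict closure)
#' that [cross_validate()] refits inside every training fold, so all
#' preprocessing (undersampling, feature selection, scaling, pretraining,
#' fine-tuning, SVM fitting) is leakage-safe by default.
#'
#' `learner_svm()` is a plain SVM on the (optionally top-variance-selected)
#' expression values. `learner_dbn()` is a DBN classifier. `learner_hybrid()`
#' is the combined classifier: a deep representation (`source` as in
#' [representation_extractor()]) feeding an SVM; with
#' `source = "passthrough"` it reduces exactly to `learner_svm()`.
#'
#' @param kernel,cost,gamma SVM settings (see [hybrid_classifier()]).
#' @param select_k optional top-variance gene count, applied within the
#'   training fold (or hoisted globally by `cross_validate(selection_scope =
#'   "global")`).
#' @param architecture,control,cd,encoding,pretrain DBN settings (see
#'   [dbn()]).
#' @param hidden encoder sizes for `learner_hybrid(source = "autoencoder")`.
#' @param source representation source for the hybrid learner.
#' @param layer_index hidden layer fed to the SVM; default last hidden /
#'   code layer.
#' @return A `cv_learner` object.
#' @name learners
NULL

#' @rdname learners
#' @export
learner_svm <- function(kernel = "linear", cost = 1, gamma = NULL, select_k = NULL) {
  new_learner(
    name = sprintf("svm-%s", kernel),
    fit = function(ds, seed) {
      sel <- NULL
      x <- ds$expression
      if (!is.null(select_k)) {
        sel <- select_top_variance(ds, select_k)
        x <- x[, sel$indices, drop = FALSE]
      }
      ext <- representation_extractor("passthrough")
      list(model = hybrid_classifier(x, ds$labels, ext, kernel = kernel,
                                     cost = cost, gamma = gamma),
           selection = sel)
    },
    predict = function(fit, ds) {
      x <- ds$expression
      if (!is.null(fit$selection)) x <- x[, fit$selection$indices, drop = FALSE]
      predict(fit$model, x)
    },
    select_k = select_k
  )
}

#' @rdname learners
#' @export
learner_dbn <- function(architecture = "A-50-10-1", control = train_control(),
                        cd = cd_control(), encoding = NULL, pretrain = TRUE,
                        select_k = NULL) {
  new_learner(
    name = sprintf("dbn-%s", control$algorithm),
    fit = function(ds, seed) {
      dbn(ds, architecture = architecture, control = control, cd = cd,
          encoding = encoding, pretrain = pretrain, select_k = select_k,
          seed = seed)
    },
    predict = function(fit, ds) predict(fit, ds),
    select_k = select_k
  )
}

#' @rdname learners
#' @export
learner_hybrid <- function(source = "finetuned-dbn", architecture = "A-50-10-1",
                           control = train_control(), cd = cd_control(),
                           encoding = NULL, pretrain = TRUE, hidden = c(50, 10),
                           layer_index = NULL, kernel = "linear", cost = 1,
                           gamma = NULL, select_k = NULL) {
  fit_fun <- switch(source,
    "passthrough" = NULL,
    "finetuned-dbn" = ,
    "pretrained-stack" = function(ds, seed) {
      ctl <- control
      if (source == "pretrained-stack") ctl$epochs <- 0L  # representation from pretraining only
      base <- dbn(ds, architecture = architecture, control = ctl, cd = cd,
                  encoding = encoding, pretrain = TRUE, select_k = select_k,
                  seed = seed)
      ext <- representation_extractor(source, base, layer_index)
      hybrid_classifier(ds, extractor = ext, kernel = kernel, cost = cost,
                        gamma = gamma)
    },
    "autoencoder" = function(ds, seed) {
      base <- autoencoder(ds, hidden = hidden, control = control, cd = cd,
                          select_k = select_k, seed = seed)
      ext <- representation_extractor("autoencoder", base)
      hybrid_classifier(ds, extractor = ext, kernel = kernel, cost = cost,
                        gamma = gamma)
    },
    stop("unknown hybrid source: ", source, call. = FALSE)
  )
  if (identical(source, "passthrough")) {
    return(learner_svm(kernel = kernel, cost = cost, gamma = gamma,
                       select_k = select_k))
  }
  new_learner(
    name = sprintf("%s+svm-%s", source, kernel),
    fit = fit_fun,
    predict = function(fit, ds) predict(fit, ds),
    select_k = select_k
  )
}

# ---- cross-validated evaluation ------------------------------------------

#' Cross-validated evaluation with class balancing
#'
#' The evaluation protocol used throughout the package: the data are split
#' once into `k` disjoint folds (stratified by class by default); for each
#' fold the remaining `k - 1` folds form the training set, which is balanced
#' by [undersample()] when `balance = TRUE` (test folds are never touched,
#' so reported metrics reflect the natural class balance); the learner is
#' refit from scratch on the training portion and evaluated on the held-out
#' fold. Accuracy, sensitivity, specificity and error rate are computed per
#' fold; the report carries their means and standard errors
#' (`sd / sqrt(k)`).
#'
#' @param ds a labeled [expression_dataset()].
#' @param learner a `cv_learner` (see [learners]).
#' @param k number of folds (default 10).
#' @param balance undersample the training folds to equal class sizes.
#' @param stratify stratified fold assignment (recommended with small
#'   classes); plain random folds when `FALSE`.
#' @param selection_scope `"fold"` computes any feature selection inside the
#'   training folds only (no leakage, the default); `"global"` performs the
#'   learner's top-variance selection once on the whole dataset before
#'   splitting, mimicking a whole-dataset selection.
#' @param positive label treated as positive for sensitivity/specificity
#'   (binary tasks); default is the first factor level.
#' @param seed integer seed; the full report is a deterministic function of
#'   it.
#' @return Object of class `cv_report`: list with `folds` (per-fold counts
#'   and metrics), `summary` (mean and standard error per metric),
#'   `per_class` (one-vs-rest sensitivity per class, 3-class tasks),
#'   `k`, `positive`, `learner`.
#' @export
cross_validate <- function(ds, learner, k = 10, balance = TRUE, stratify = TRUE,
                           selection_scope = c("fold", "global"),
                           positive = NULL, seed = 1) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(learner, "cv_learner"))
  selection_scope <- match.arg(selection_scope)
  if (is.null(ds$labels)) stop("cross_validate needs a labeled dataset", call. = FALSE)
  y <- droplevels(ds$labels)
  ds <- expression_dataset(ds$expression, labels = y)
  if (selection_scope == "global" && !is.null(learner$select_k)) {
    # hoist the learner's top-variance selection to the whole dataset; any
    # re-selection inside folds then keeps all remaining genes (identity up
    # to gene order, which fit/predict apply consistently)
    sel <- select_top_variance(ds, learner$select_k)
    ds <- subset_genes(ds, sel$indices)
  }
  n <- nrow(ds$expression)
  folds <- kfold_split(n, k, labels = if (stratify) y, seed = derive_seed(seed, 0))
  if (is.null(positive)) positive <- levels(y)[1]
  binary <- nlevels(y) == 2L
  fold_rows <- vector("list", k)
  per_class <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds$fold == f
    ds_tr <- subset_samples(ds, which(!te))
    ds_te <- subset_samples(ds, which(te))
    if (nlevels(droplevels(ds_tr$labels)) < nlevels(y)) {
      stop(sprintf(paste0("fold %d lost a class from its training data; ",
                          "use stratify = TRUE or fewer folds"), f), call. = FALSE)
    }
    if (balance) ds_tr <- undersample(ds_tr, seed = derive_seed(seed, 100 + f))
    fit <- learner$fit(ds_tr, derive_seed(seed, 200 + f))
    pred <- learner$predict(fit, ds_te)
    truth <- ds_te$labels
    acc <- mean(as.character(pred) == as.character(truth))
    if (binary) {
      cc <- confusion_counts(pred, truth, positive)
      met <- classification_metrics(cc)
      fold_rows[[f]] <- data.frame(fold = f, n_test = length(truth),
                                   tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
                                   accuracy = met$accuracy, tpr = met$tpr,
                                   tnr = met$tnr, error_rate = met$error_rate)
    } else {
      fold_rows[[f]] <- data.frame(fold = f, n_test = length(truth),
                                   tp = NA, tn = NA, fp = NA, fn = NA,
                                   accuracy = acc, tpr = NA_real_, tnr = NA_real_,
                                   error_rate = 1 - acc)
      per_class[[f]] <- do.call(rbind, lapply(levels(y), function(cl) {
        m <- classification_metrics(confusion_counts(pred, truth, cl))
        data.frame(fold = f, class = cl, tpr = m$tpr, tnr = m$tnr)
      }))
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  summarize <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(mean = NA_real_, se = NA_real_))
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  }
  metrics <- c("accuracy", "tpr", "tnr", "error_rate")
  summ <- do.call(rbind, lapply(metrics, function(mname) {
    s <- summarize(folds_df[[mname]])
    data.frame(metric = mname, mean = s["mean"], se = s["se"], row.names = NULL)
  }))
  structure(list(folds = folds_df, summary = summ,
                 per_class = if (!binary) do.call(rbind, per_class),
                 k = k, positive = positive, learner = learner$name,
                 balance = balance, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: %s%s\n", x$k, x$learner,
              if (x$balance) " (undersampled training folds)" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (!is.na(s$mean[i])) {
      cat(sprintf("  %-11s %6.2f%% +/- %.2f%%\n", s$metric[i],
                  100 * s$mean[i], 100 * s$se[i]))
    }
  }
  if (!is.null(x$per_class)) {
    agg <- stats::aggregate(tpr ~ class, data = x$per_class, FUN = mean)
    cat("  per-class sensitivity (one-vs-rest):",
        paste(sprintf("%s %.2f%%", agg$class, 100 * agg$tpr), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cross-validation report as delimited text
#'
#' Writes a long-format TSV (`metric`, `fold`, `value`) plus a summary TSV
#' (`metric`, `mean`, `se`) mirroring the classifier x task x Acc +/- SE
#' presentation of results tables.
#'
#' @param report a `cv_report`.
#' @param prefix output path prefix; writes `<prefix>_folds.tsv` and
#'   `<prefix>_summary.tsv`.
#' @return The written paths, invisibly.
#' @export
write_cv_report <- function(report, prefix) {
  stopifnot(inherits(report, "cv_report"))
  long <- do.call(rbind, lapply(c("accuracy", "tpr", "tnr", "error_rate"),
                                function(mname) {
    data.frame(metric = mname, fold = report$folds$fold,
               value = report$folds[[mname]])
  }))
  f1 <- paste0(prefix, "_folds.tsv")
  f2 <- paste0(prefix, "_summary.tsv")
  utils::write.table(long, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
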