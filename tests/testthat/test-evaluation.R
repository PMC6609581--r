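test_that("confusion counts are the standard contingency tallies", {
  cc <- confusion_counts(rep(c("p", "n"), c(5, 5)), rep(c("p", "n"), c(5, 5)), "p")
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 5L, tn = 5L, fp = 0L, fn = 0L))
  cc2 <- confusion_counts(rep("p", 10), rep(c("p", "n"), c(3, 7)), "p")
  expect_equal(unlist(cc2[c("tp", "fp", "tn", "fn")]),
               c(tp = 3L, fp = 7L, tn = 0L, fn = 0L))
  expect_error(confusion_counts(character(0), character(0), "p"), "no samples")
  expect_error(confusion_counts(c("p"), c("p", "n"), "p"), "equal length")
})

test_that("metrics reproduce the hand-computed table and stay undefined at 0/0", {
  cc <- structure(list(tp = 3, tn = 2, fp = 1, fn = 4), class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$tpr, 3 / 7)
  expect_equal(m$tnr, 2 / 3)
  expect_equal(m$error_rate, 0.5)

  perfect <- classification_metrics(
    structure(list(tp = 5, tn = 5, fp = 0, fn = 0), class = "confusion_counts"))
  expect_equal(unlist(perfect), c(accuracy = 1, tpr = 1, tnr = 1, error_rate = 0))

  nopos <- classification_metrics(
    structure(list(tp = 0, tn = 4, fp = 2, fn = 0), class = "confusion_counts"))
  expect_true(is.na(nopos$tpr))
  expect_false(is.na(nopos$tnr))
})

test_that("accuracy and error rate sum exactly to one over random tables", {
  set.seed(2)
  for (i in 1:25) {
    counts <- as.list(stats::setNames(rpois(4, 5) + c(1, 1, 0, 0),
                                      c("tp", "tn", "fp", "fn")))
    m <- classification_metrics(structure(counts, class = "confusion_counts"))
    expect_identical(m$accuracy + m$error_rate, 1)
    # accuracy decomposes over the two rates when both are defined
    if (!is.na(m$tpr) && !is.na(m$tnr)) {
      total <- counts$tp + counts$tn + counts$fp + counts$fn
      expect_equal(m$accuracy,
                   (m$tpr * (counts$tp + counts$fn) +
                      m$tnr * (counts$tn + counts$fp)) / total)
    }
  }
})

test_that("cross-validation is perfect on cleanly separable data", {
  ds <- simulate_expression(c(30, 30), n_genes = 40, n_differential = 10,
                            effect_size = 6, noise_sd = 1, seed = 30)$dataset
  rep <- cross_validate(ds, learner_svm(), k = 10, seed = 3)
  s <- rep$summary[rep$summary$metric == "accuracy", ]
  expect_equal(s$mean, 1)
  expect_equal(s$se, 0)
  expect_equal(nrow(rep$folds), 10L)
})

test_that("label-permuted data score at chance level", {
  ds <- simulate_expression(c(30, 30), n_genes = 40, n_differential = 10,
                            effect_size = 6, noise_sd = 1, seed = 31)$dataset
  set.seed(7)
  ds_null <- expression_dataset(ds$expression, labels = sample(ds$labels))
  rep <- cross_validate(ds_null, learner_svm(), k = 10, seed = 5)
  s <- rep$summary[rep$summary$metric == "accuracy", ]
  expect_lt(abs(s$mean - 0.5), 3 * s$se)
})

test_that("reports are bit-for-bit reproducible under a fixed seed", {
  ds <- tiny_labeled_dataset(n_per_class = 12, n_genes = 20, seed = 33)
  ln <- learner_dbn(architecture = "A-5-1",
                    control = train_control("rprop", epochs = 10),
                    cd = cd_control(epochs = 2))
  r1 <- cross_validate(ds, ln, k = 4, seed = 8)
  r2 <- cross_validate(ds, ln, k = 4, seed = 8)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$summary, r2$summary)
  r3 <- cross_validate(ds, ln, k = 4, seed = 9)
  expect_false(identical(r1$folds, r3$folds))
})

test_that("a training fold losing a class is an actionable error", {
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  ds <- expression_dataset(x, labels = rep(c("a", "b"), c(9, 1)))
  expect_error(cross_validate(ds, learner_svm(), k = 10, stratify = FALSE,
                              balance = FALSE, seed = 1),
               "stratif")
})

test_that("three-class evaluation reports overall accuracy and per-class rates", {
  ds <- simulate_expression(c(20, 20, 20), n_genes = 30, n_differential = 8,
                            effect_size = 5, seed = 35)$dataset
  rep <- cross_validate(ds, learner_svm(), k = 5, seed = 2)
  s <- rep$summary[rep$summary$metric == "accuracy", ]
  expect_gt(s$mean, 0.9)
  expect_s3_class(rep$per_class, "data.frame")
  expect_setequal(unique(rep$per_class$class), c("class1", "class2", "class3"))
  # accuracy + error rate = 1 per fold, multiclass included
  expect_identical(rep$folds$accuracy + rep$folds$error_rate, rep(1, 5))
})

test_that("global selection scope mimics whole-dataset selection", {
  ds <- tiny_labeled_dataset(n_per_class = 15, n_genes = 50, seed = 36)
  rep_fold <- cross_validate(ds, learner_svm(select_k = 10), k = 5,
                             selection_scope = "fold", seed = 4)
  rep_glob <- cross_validate(ds, learner_svm(select_k = 10), k = 5,
                             selection_scope = "global", seed = 4)
  expect_s3_class(rep_glob, "cv_report")
  expect_equal(nrow(rep_glob$folds), 5L)
  expect_true(is.finite(rep_fold$summary$mean[1]))
})

test_that("report files carry fold-level and summary tables", {
  ds <- tiny_labeled_dataset(n_per_class = 10, n_genes = 15, seed = 37)
  rep <- cross_validate(ds, learner_svm(), k = 3, seed = 1)
  prefix <- file.path(tempdir(), "cvrep")
  paths <- write_cv_report(rep, prefix)
  folds <- read.delim(paths[1])
  expect_setequal(unique(folds$metric), c("accuracy", "tpr", "tnr", "error_rate"))
  summ <- read.delim(paths[2])
  expect_equal(summ$mean[summ$metric == "accuracy"],
               rep$summary$mean[rep$summary$metric == "accuracy"])
})
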