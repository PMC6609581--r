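test_that("expression matrices load in either orientation", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2",
               "s1\t1.5\t2.5",
               "s2\t3\t4",
               "s3\t5\t6.25"), tsv)
  ds <- read_expression_matrix(tsv)
  expect_equal(dim(ds), c(3L, 2L))
  expect_equal(rownames(ds$expression), c("s1", "s2", "s3"))
  expect_equal(unname(ds$expression["s3", "g2"]), 6.25)

  # the same data stored genes-as-rows loads to an identical dataset
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "g1\t1.5\t3\t5",
               "g2\t2.5\t4\t6.25"), tsv2)
  ds2 <- read_expression_matrix(tsv2, orientation = "genes-as-rows")
  expect_identical(ds2$expression, ds$expression)
})

test_that("malformed matrices are rejected with the offending cell named", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "s1\t1\t", "s2\t3\t4"), tsv)
  expect_error(read_expression_matrix(tsv), "s1.*g2")

  tsv3 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "s1\t1\tx", "s2\t3\t4"), tsv3)
  expect_error(read_expression_matrix(tsv3), "non-numeric")

  x <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("g1", "g1")))
  expect_error(expression_dataset(x * 1.0), "duplicate gene ids")
})

test_that("labels attach by sample id and class counts are enforced", {
  x <- matrix(rnorm(6), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("g1", "g2")))
  ds <- expression_dataset(x)
  labeled <- attach_labels(ds, c(s2 = "b", s1 = "a", s3 = "a"))
  expect_equal(as.character(labeled$labels), c("a", "b", "a"))
  expect_error(attach_labels(ds, c(s1 = "a", s2 = "b")), "s3")
  expect_error(attach_labels(ds, c(s1 = "a", s2 = "a", s3 = "a")),
               "2 or 3 classes")
})

test_that("log transform is log2(v + 1) and rejects negatives", {
  x <- matrix(c(0, 1, 3, 7), 2, 2,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  out <- log_transform(expression_dataset(x))
  expect_equal(unname(out$expression), matrix(c(0, 1, 2, 3), 2, 2))
  expect_error(log_transform(expression_dataset(x - 1)), "non-negative")
})

test_that("top-variance selection orders by variance with index tie-break", {
  x <- cbind(g1 = c(1, 1, 1), g2 = c(0, 2, 4), g3 = c(4, 2, 0), g4 = c(0, 1, 2))
  rownames(x) <- paste0("s", 1:3)
  ds <- expression_dataset(x)
  sel <- select_top_variance(ds, 1)
  expect_equal(sel$indices, 2L)  # zero-variance gene never wins
  sel3 <- select_top_variance(ds, 3)
  expect_equal(sel3$indices, c(2L, 3L, 4L))  # tie between g2/g3 -> lower index first
  expect_equal(select_top_variance(ds, 99)$indices, c(2L, 3L, 4L, 1L))
})

test_that("top-variance selection is permutation-equivariant", {
  sim <- tiny_labeled_dataset(seed = 8)
  perm <- sample(ncol(sim$expression))
  permuted <- expression_dataset(sim$expression[, perm], labels = sim$labels)
  sel <- select_top_variance(sim, 10)
  sel_p <- select_top_variance(permuted, 10)
  expect_equal(match(sel$indices, perm), sel_p$indices)
})

test_that("undersampling reduces every class to the minimum count", {
  sim <- simulate_expression(c(209, 77), n_genes = 30, n_differential = 5,
                             seed = 1)$dataset
  bal <- undersample(sim, seed = 9)
  expect_equal(unname(c(table(bal$labels))), c(77L, 77L))
  # retained set is a subset; smallest class fully kept
  expect_true(all(rownames(bal$expression) %in% rownames(sim$expression)))
  expect_setequal(rownames(bal$expression)[bal$labels == "class2"],
                  rownames(sim$expression)[sim$labels == "class2"])
  # deterministic given the seed
  expect_identical(undersample(sim, seed = 9), bal)
  expect_false(identical(undersample(sim, seed = 10), bal))

  tri <- simulate_expression(c(59, 42, 26), n_genes = 20, n_differential = 3,
                             seed = 2)$dataset
  bal3 <- undersample(tri, seed = 1)
  expect_equal(unname(c(table(bal3$labels))), c(26L, 26L, 26L))

  even <- simulate_expression(c(50, 50), n_genes = 10, n_differential = 2,
                              seed = 3)$dataset
  expect_identical(rownames(undersample(even, seed = 1)$expression),
                   rownames(even$expression))
})

test_that("k-fold assignments are disjoint, covering, and balanced", {
  f <- kfold_split(100, 10, seed = 1)
  expect_equal(unname(c(table(f$fold))), rep(10L, 10))

  f2 <- kfold_split(127, 10, seed = 1)
  expect_equal(sort(unname(c(table(f2$fold)))), c(rep(12L, 3), rep(13L, 7)))
  expect_equal(sort(unique(f2$fold)), 1:10)

  expect_error(kfold_split(10, 11), "folds")

  # stratified: per-class counts differ by at most one across folds
  y <- rep(c("a", "b", "c"), c(59, 42, 26))
  fs <- kfold_split(127, 10, labels = y, seed = 5)
  for (cl in unique(y)) {
    per_fold <- table(factor(fs$fold[y == cl], levels = 1:10))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_lte(diff(range(table(fs$fold))), 1)
})

test_that("datasets round-trip through the TSV pair exactly", {
  sim <- tiny_labeled_dataset(seed = 77)
  prefix <- file.path(tempdir(), "roundtrip")
  write_expression_dataset(sim, prefix)
  back <- read_expression_dataset(prefix)
  expect_identical(back$expression, sim$expression)
  expect_identical(as.character(back$labels), as.character(sim$labels))
})
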