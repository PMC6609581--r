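#' Simulate log-scale expression data with known class structure
#'
#' Generates a samples x genes matrix mimicking log2-scale microarray
#' intensities: each gene g draws a baseline mean mu_g ~ Normal(baseline_mean,
#' baseline_sd), every class beyond the first shifts its own disjoint block of
#' `n_differential` genes upward by `effect_size`, and sample values are drawn
#' Normal(class mean, noise_sd). The generator is the test bed for every
#' classifier in the package: the differential gene indices are returned as
#' ground truth.
#'
#' @param n_per_class integer vector of class sizes (2 or 3 classes);
#'   unbalanced designs such as `c(209, 77)` are supported directly.
#' @param n_genes number of genes.
#' @param n_differential number of genes shifted per class contrast (each
#'   non-reference class gets its own disjoint block).
#' @param effect_size shift delta in log2 units added to a differential gene
#'   in its class.
#' @param noise_sd within-class standard deviation sigma (log2 units).
#' @param baseline_mean,baseline_sd parameters of the per-gene baseline mean
#'   distribution; defaults Normal(8, 2) match typical log2 microarray
#'   intensities.
#' @param class_names optional class names; defaults to `"class1"`, ...
#' @param correlation optional list `list(genes = <count>, rho = <0..1>)`: the
#'   first `genes` genes share a per-sample common factor so that every pair
#'   of them has noise correlation `rho` (marginal noise variance is
#'   preserved). Off (`NULL`) by default: real arrays show co-expression,
#'   but uncorrelated noise is the cleaner default for method checks.
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @return A list with `dataset` (labeled [expression_dataset()]) and
#'   `differential` (named list of ground-truth shifted gene indices per
#'   non-reference class).
#' @examples
#' sim <- simulate_expression(c(20, 20), n_genes = 100, n_differential = 10,
#'                            effect_size = 2, seed = 1)
#' sim$dataset
#' @export
simulate_expression <- function(n_per_class, n_genes, n_differential,
                                effect_size = 1, noise_sd = 1,
                                baseline_mean = 8, baseline_sd = 2,
                                class_names = NULL, correlation = NULL,
                                seed = NULL) {
  if (length(n_per_class) < 2L || length(n_per_class) > 3L || any(n_per_class < 1)) {
    stop("'n_per_class' must give 2 or 3 positive class sizes", call. = FALSE)
  }
  stop_if_not_scalar_number(n_genes, "n_genes", lower = 1)
  stop_if_not_scalar_number(n_differential, "n_differential", lower = 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0", call. = FALSE)
  n_classes <- length(n_per_class)
  if ((n_classes - 1L) * n_differential > n_genes) {
    stop("need n_differential disjoint genes per non-reference class", call. = FALSE)
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  n <- sum(n_per_class)
  with_seed(seed, {
    mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    labels <- factor(rep(class_names, n_per_class), levels = class_names)
    # disjoint differential blocks, one per non-reference class
    differential <- list()
    pool <- seq_len(n_genes)
    for (c in seq_len(n_classes)[-1]) {
      idx <- sort(sample(pool, n_differential))
      pool <- setdiff(pool, idx)
      differential[[class_names[c]]] <- idx
    }
    x <- matrix(stats::rnorm(n * n_genes, sd = noise_sd), n, n_genes)
    if (!is.null(correlation)) {
      nb <- correlation$genes
      rho <- correlation$rho
      if (is.null(nb) || is.null(rho) || nb > n_genes || rho < 0 || rho >= 1) {
        stop("'correlation' needs genes <= n_genes and rho in [0, 1)", call. = FALSE)
      }
      common <- stats::rnorm(n, sd = noise_sd)
      x[, seq_len(nb)] <- sqrt(rho) * common +
        sqrt(1 - rho) * x[, seq_len(nb), drop = FALSE]
    }
    x <- sweep(x, 2, mu, "+")
    for (c in seq_len(n_classes)[-1]) {
      rows <- which(labels == class_names[c])
      cols <- differential[[class_names[c]]]
      if (length(cols)) x[rows, cols] <- x[rows, cols] + effect_size
    }
    ds <- expression_dataset(
      x,
      sample_ids = sprintf("s%03d", seq_len(n)),
      gene_ids = sprintf("g%04d", seq_len(n_genes)),
      labels = labels
    )
    list(dataset = ds, differential = differential)
  })
}
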