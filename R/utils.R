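# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Logistic activation and its derivative expressed through the activation
# value (a * (1 - a)), which is what backpropagation needs.
logistic <- function(x) stats::plogis(x)
logistic_prime_from_activation <- function(a) a * (1 - a)

# All randomness in a composite run flows from one top-level seed, fanned out
# deterministically per component/fold. Offsets are small so derived seeds
# stay well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# Column variances without forming a centred copy per column group.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

log_line <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", sprintf(...))
  }
  invisible(NULL)
}
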