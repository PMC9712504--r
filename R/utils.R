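# Internal helpers shared across modules.

# Draw from a zero-truncated negative binomial (gamma-Poisson) via inverse CDF.
# Guarantees counts >= 1 so positivity planted by the simulator is exact.
rztnbinom <- function(n, mu, size) {
  if (n == 0L) return(integer(0))
  p0 <- pnbinom(0, mu = mu, size = size)
  u <- runif(n, min = p0, max = 1)
  pmax(qnbinom(u, mu = mu, size = size), 1L)
}

# Coerce a counts input to dgCMatrix with dimnames, genes x cells.
as_counts <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix must carry gene rownames and cell colnames")
  }
  as(as(x, "CsparseMatrix"), "dMatrix")
}

# Column sums that work for both dense and sparse inputs.
col_totals <- function(x) {
  if (inherits(x, "Matrix")) Matrix::colSums(x) else colSums(x)
}

row_means_subset <- function(x, cols) {
  if (inherits(x, "Matrix")) Matrix::rowMeans(x[, cols, drop = FALSE])
  else rowMeans(x[, cols, drop = FALSE])
}

# Integer seed derived from a base seed and a stream index, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 9973) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must be a single value in [0, 1]")
  }
}
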