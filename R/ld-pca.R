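#' Pairwise linkage disequilibrium as Pearson correlation
#'
#' LD between two positions is the Pearson correlation of their genotype
#' columns over all individuals (cases and controls together). Columns
#' with zero variance are degenerate SNPs and raise an error.
#'
#' @param g A [genotype_matrix].
#' @param i,j Position (column) indices.
#' @return Correlation in `[-1, 1]`.
#' @export
compute_ld <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  L <- ncol(g$values)
  if (i < 1L || i > L || j < 1L || j > L) stop("position index out of range")
  xi <- g$values[, i]
  xj <- g$values[, j]
  if (stats::var(xi) == 0) stop("zero-variance (degenerate) SNP at position ", i)
  if (stats::var(xj) == 0) stop("zero-variance (degenerate) SNP at position ", j)
  stats::cor(xi, xj)
}

# Absolute-correlation matrix over a set of columns; zero-variance columns
# are reported back as attribute "dropped" with NA correlations.
ld_matrix <- function(g, positions) {
  x <- g$values[, positions, drop = FALSE]
  v <- apply(x, 2L, stats::var)
  dropped <- positions[v == 0]
  r <- suppressWarnings(stats::cor(x))
  attr(r, "dropped") <- dropped
  r
}

#' Principal-component covariates from genotypes
#'
#' Standardises genotype columns (mean 0, unit variance; zero-variance
#' columns are dropped with a message) and returns the leading `k`
#' principal-component scores per individual, for use as population
#' structure covariates in association testing.
#'
#' @param g A [genotype_matrix].
#' @param k Number of components (`k = 0` returns a 0-column matrix).
#' @return Numeric matrix (n_individuals x k) with columns `PC1..PCk`.
#' @export
pca_covariates <- function(g, k) {
  stopifnot(inherits(g, "genotype_matrix"), k >= 0L)
  n <- nrow(g$values)
  if (k == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0L,
                  dimnames = list(g$sample_ids, NULL)))
  }
  x <- g$values
  storage.mode(x) <- "double"
  v <- matrixStats_colVars(x)
  keep <- v > 0
  if (any(!keep)) {
    message(sum(!keep), " zero-variance column(s) dropped before PCA")
    x <- x[, keep, drop = FALSE]
  }
  if (k > min(n, ncol(x))) stop("k exceeds the rank bound min(n, positions)")
  xs <- scale(x)
  # scores via the n x n Gram matrix: cheap when n << L
  gram <- tcrossprod(xs)
  eig <- eigen(gram, symmetric = TRUE)
  pos <- sum(eig$values > max(eig$values) * 1e-9)
  if (k > pos) stop("k exceeds the numerical rank (", pos, ")")
  scores <- eig$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(pmax(eig$values[seq_len(k)], 0)), each = n)
  dimnames(scores) <- list(g$sample_ids, paste0("PC", seq_len(k)))
  scores
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}
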