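#' Simulate a continuous phenotype with nonlinear genetic effects
#'
#' The continuous phenotype for individual i is the sum of four genetic
#' terms plus Gaussian noise:
#' \deqn{Y_i = \sum_{j \in D} f^D_j(X_{ij}) + \sum_{j \in R} f^R_j(X_{ij})
#'   + \sum_{(j,k)} \beta_{jk} X_{ij} X_{ik}
#'   + \sum_{(j,k,l)} \beta_{jkl} X_{ij} X_{ik} X_{il} + \epsilon_i}
#' with a dominant contribution \eqn{f^D_j = \beta_j X_{ij}} unless
#' \eqn{X_{ij} = -1} (then 0), a recessive contribution
#' \eqn{f^R_j = \beta_j X_{ij}} only when \eqn{X_{ij} = 1} (else 0), and
#' \eqn{\epsilon_i \sim N(0, k\sigma^2)} where \eqn{\sigma^2} is the
#' empirical (population) variance of the total genetic effect over the
#' cohort and `k` scales the noise. `k = 0` returns the genetic sum
#' exactly.
#'
#' @param g A [genotype_matrix].
#' @param e An `effect_spec` from [assign_effects()].
#' @param k Non-negative noise scaling factor.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `phenotype_set` (continuous part) with
#'   `y_continuous`, `genetic_sum`, `sigma2_genetic`, `k`, `epsilon_seed`.
#' @export
simulate_continuous <- function(g, e, k = 1, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(e, "effect_spec"))
  if (k < 0) stop("noise scaling factor k must be >= 0")
  L <- ncol(g$values)
  if (any(causal_positions(e) > L)) stop("effect positions exceed matrix size")
  X <- g$values
  storage.mode(X) <- "double"
  gsum <- numeric(nrow(X))
  for (i in seq_along(e$dominant)) {
    j <- e$dominant[i]
    b <- e$beta_single[[as.character(j)]]
    xj <- X[, j]
    gsum <- gsum + ifelse(xj == -1, 0, b * xj)
  }
  for (i in seq_along(e$recessive)) {
    j <- e$recessive[i]
    b <- e$beta_single[[as.character(j)]]
    xj <- X[, j]
    gsum <- gsum + ifelse(xj == 1, b * xj, 0)
  }
  for (i in seq_len(nrow(e$pairs))) {
    gsum <- gsum + e$beta_pair[i] * X[, e$pairs[i, 1]] * X[, e$pairs[i, 2]]
  }
  for (i in seq_len(nrow(e$triplets))) {
    gsum <- gsum + e$beta_triplet[i] *
      X[, e$triplets[i, 1]] * X[, e$triplets[i, 2]] * X[, e$triplets[i, 3]]
  }
  names(gsum) <- NULL
  sigma2 <- pop_var(gsum)
  noise_var <- k * sigma2
  eps <- if (noise_var > 0) {
    with_seed(seed, stats::rnorm(nrow(X), 0, sqrt(noise_var)))
  } else {
    numeric(nrow(X))
  }
  structure(
    list(y_continuous = gsum + eps, genetic_sum = gsum,
         sigma2_genetic = sigma2, k = k, epsilon_seed = as.integer(seed),
         sample_ids = g$sample_ids),
    class = "phenotype_set"
  )
}

#' Binarize a continuous phenotype by a case-count threshold
#'
#' Sets the threshold tau to the (n_cases + 1)-th largest phenotype value
#' so that exactly `n_cases` individuals satisfy `y > tau` (case label 1).
#' If the order statistic is tied with higher values, the strict rule may
#' yield fewer cases and a warning is raised; real-valued phenotypes make
#' this a measure-zero event.
#'
#' @param y Numeric vector of continuous phenotypes.
#' @param n_cases Target number of cases, `0 < n_cases < length(y)`.
#' @return List with `y_binary` (integer 0/1) and `tau`.
#' @export
binarize <- function(y, n_cases) {
  n <- length(y)
  if (n_cases <= 0 || n_cases >= n) {
    stop("n_cases must be strictly between 0 and ", n)
  }
  if (diff(range(y)) == 0) stop("phenotype values are all equal; threshold undefined")
  tau <- sort(y, decreasing = TRUE)[n_cases + 1L]
  b <- as.integer(y > tau)
  if (sum(b) != n_cases) {
    warning("ties at the threshold: ", sum(b), " cases instead of ", n_cases)
  }
  list(y_binary = b, tau = tau)
}

#' Simulate a binarized phenotype in one call
#'
#' Convenience wrapper chaining [simulate_continuous()] and [binarize()].
#' The default case fraction 0.1985 mirrors a cohort of ~1814 cases among
#' 9139 individuals.
#'
#' @inheritParams simulate_continuous
#' @param case_fraction Fraction of individuals labelled case (used when
#'   `n_cases` is `NULL`).
#' @param n_cases Explicit case count, overrides `case_fraction`.
#' @return A full `phenotype_set` with `y_binary` and `tau` added.
#' @export
simulate_phenotypes <- function(g, e, k = 1, seed = 1L,
                                case_fraction = 1814 / 9139, n_cases = NULL) {
  ps <- simulate_continuous(g, e, k = k, seed = seed)
  if (is.null(n_cases)) {
    n_cases <- max(1L, round(length(ps$y_continuous) * case_fraction))
  }
  bz <- binarize(ps$y_continuous, n_cases)
  ps$y_binary <- bz$y_binary
  ps$tau <- bz$tau
  ps
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat("phenotype_set:", length(x$y_continuous), "individuals\n")
  cat(sprintf("  sigma2_genetic = %.4g, k = %g\n", x$sigma2_genetic, x$k))
  if (!is.null(x$y_binary)) {
    cat("  cases:", sum(x$y_binary), " controls:", sum(1 - x$y_binary), "\n")
  }
  invisible(x)
}

#' Write phenotypes as TSV
#' @param ps A `phenotype_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(ps, path) {
  tab <- data.frame(sample_id = ps$sample_ids,
                    y_continuous = ps$y_continuous,
                    y_binary = ps$y_binary %||% NA_integer_)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phenotypes from TSV
#' @param path TSV written by [write_phenotypes()].
#' @return A data.frame with sample_id, y_continuous, y_binary.
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
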