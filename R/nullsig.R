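#' Pool null MAS vectors from permuted-label models
#'
#' @param null_mas List of `mas_vector`s obtained from models trained on
#'   permuted labels (equal lengths required).
#' @return Numeric vector of length `m_null * L`.
#' @export
pool_null_mas <- function(null_mas) {
  stopifnot(length(null_mas) >= 1L)
  vals <- lapply(null_mas, function(m) {
    if (inherits(m, "mas_vector")) m$values else as.numeric(m)
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) {
    stop("null MAS vectors differ in length: ", paste(unique(lens), collapse = ", "))
  }
  unlist(vals, use.names = FALSE)
}

#' Fit a half-normal scale to pooled null scores
#'
#' MAS values are absolute means over many samples, so under permuted
#' labels a central-limit argument suggests a folded normal centred at
#' zero — a half-normal. Its maximum-likelihood scale is
#' `sigma_hat = sqrt(mean(x^2))`.
#'
#' @param pooled Non-negative numeric vector (not all zero).
#' @param tail_only Optionally fit on the values above this quantile of
#'   the pool (in (0,1)) instead of the full pool; `NULL` (default) uses
#'   everything.
#' @return A `null_model` with `sigma`, `n_pooled` and an empty
#'   `fit_table` (see [compare_tail_distributions()]).
#' @export
fit_halfnormal <- function(pooled, tail_only = NULL) {
  if (length(pooled) == 0L) stop("empty pool")
  if (any(pooled < 0)) stop("null MAS values must be non-negative")
  x <- pooled
  if (!is.null(tail_only)) {
    x <- x[x > stats::quantile(x, tail_only)]
  }
  if (all(x == 0)) stop("all pooled values are zero; scale undefined")
  structure(
    list(sigma = sqrt(mean(x^2)), n_pooled = length(pooled),
         tail_quantile = tail_only, fit_table = NULL),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null_model: half-normal sigma = %.4g (pooled n = %d)\n",
              x$sigma, x$n_pooled))
  if (!is.null(x$fit_table)) {
    print(x$fit_table, row.names = FALSE)
  }
  invisible(x)
}

# Truncated log-likelihood helpers: density f and CDF F of each candidate
# evaluated on tail values x > u, contributing
# sum log f(x) - n log(1 - F(u)). The truncation adjustment makes the
# comparison meaningful on a tail subset: the data-generating family
# attains the best expected fit.
tail_candidates <- function(u) {
  list(
    "half-normal" = list(
      k = 1L, start = 1,
      logf = function(x, p) stats::dnorm(x, 0, exp(p[1]), log = TRUE) + log(2),
      logS = function(p) log(2 * stats::pnorm(u, 0, exp(p[1]), lower.tail = FALSE))),
    "generalized-Pareto" = list(
      k = 2L, start = c(0, 0.1),
      logf = function(x, p) {
        xi <- p[1]; beta <- exp(p[2]); z <- (x - u) / beta
        if (abs(xi) < 1e-9) return(-log(beta) - z)
        arg <- 1 + xi * z
        ifelse(arg > 0, -log(beta) - (1 / xi + 1) * log(pmax(arg, 1e-300)), -Inf)
      },
      logS = function(p) 0),
    gamma = list(
      k = 2L, start = c(0, 0),
      logf = function(x, p) stats::dgamma(x, exp(p[1]), rate = exp(p[2]), log = TRUE),
      logS = function(p) stats::pgamma(u, exp(p[1]), rate = exp(p[2]),
                                       lower.tail = FALSE, log.p = TRUE)),
    exponential = list(
      k = 1L, start = 0,
      logf = function(x, p) stats::dexp(x, exp(p[1]), log = TRUE),
      logS = function(p) stats::pexp(u, exp(p[1]), lower.tail = FALSE, log.p = TRUE)),
    weibull = list(
      k = 2L, start = c(0, 0),
      logf = function(x, p) stats::dweibull(x, exp(p[1]), exp(p[2]), log = TRUE),
      logS = function(p) stats::pweibull(u, exp(p[1]), exp(p[2]),
                                         lower.tail = FALSE, log.p = TRUE)),
    lognormal = list(
      k = 2L, start = c(0, 0),
      logf = function(x, p) stats::dlnorm(x, p[1], exp(p[2]), log = TRUE),
      logS = function(p) stats::plnorm(u, p[1], exp(p[2]),
                                       lower.tail = FALSE, log.p = TRUE))
  )
}

#' Compare candidate distributions on the pool's tail
#'
#' Fits each candidate family by maximum likelihood to the tail subset
#' (values above the `tail_quantile` quantile of the pool), using the
#' truncated likelihood `f(x) / (1 - F(u))` so that families defined on
#' the whole positive axis compete fairly with the threshold-anchored
#' generalized Pareto. Reports AIC = 2k - 2logL and
#' BIC = k log(n) - 2logL per candidate.
#'
#' @param pooled Numeric pool of null scores.
#' @param tail_quantile Quantile in (0, 1) defining the tail (default
#'   0.999).
#' @param candidates Character subset of the six supported families.
#' @param min_tail Minimum number of tail points required (default 50).
#' @return A data.frame `fit_table` with columns `name`, `k`, `logLik`,
#'   `AIC`, `BIC`, sorted by AIC.
#' @export
compare_tail_distributions <- function(pooled, tail_quantile = 0.999,
                                       candidates = c("half-normal",
                                                      "generalized-Pareto",
                                                      "gamma", "exponential",
                                                      "weibull", "lognormal"),
                                       min_tail = 50L) {
  u <- stats::quantile(pooled, tail_quantile, names = FALSE)
  x <- pooled[pooled > u]
  n <- length(x)
  if (n < min_tail) {
    stop("tail subset has only ", n, " points (< ", min_tail, ")")
  }
  if (diff(range(x)) == 0) stop("degenerate tail: all values equal")
  cands <- tail_candidates(u)
  candidates <- match.arg(candidates, names(cands), several.ok = TRUE)
  rows <- lapply(candidates, function(nm) {
    cand <- cands[[nm]]
    nll <- function(p) {
      ll <- sum(cand$logf(x, p)) - n * cand$logS(p)
      if (!is.finite(ll)) 1e10 else -ll
    }
    fit <- if (cand$k == 1L) {
      stats::optim(cand$start, nll, method = "Brent", lower = -30, upper = 30)
    } else {
      stats::optim(cand$start, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10))
    }
    ll <- -fit$value
    data.frame(name = nm, k = cand$k, logLik = ll,
               AIC = 2 * cand$k - 2 * ll,
               BIC = cand$k * log(n) - 2 * ll,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$AIC), , drop = FALSE]
}

#' Attach a tail fit table to a null model
#' @param null A `null_model`.
#' @param pooled The pooled null scores it was fitted on.
#' @param ... Passed to [compare_tail_distributions()].
#' @return The `null_model` with `fit_table` filled.
#' @export
with_fit_table <- function(null, pooled, ...) {
  null$fit_table <- compare_tail_distributions(pooled, ...)
  null
}

#' Reorder a sampled vector to match observed ranks
#'
#' Returns a permutation of `sampled` whose rank order equals the rank
#' order of `observed` (the largest sampled value is placed at the argmax
#' of the observed vector, and so on). Ties in `observed` are broken by
#' position index. Rank matching transfers the dependence structure of
#' the observed scores (LD, shared architecture) onto independent null
#' draws.
#'
#' @param sampled,observed Numeric vectors of equal length.
#' @return The reordered `sampled` vector.
#' @export
rank_match <- function(sampled, observed) {
  if (length(sampled) != length(observed)) stop("length mismatch")
  out <- numeric(length(sampled))
  out[order(observed)] <- sort(sampled)
  out
}

#' Estimate P-values for AMAS by rank-matched null resampling
#'
#' Repeats `n_reps` times: draw m half-normal(sigma) score vectors of
#' length L; rank-match each to the corresponding observed MAS row;
#' average them into a null mu; recompute theta with the same percentile
#' rule on the null mu; compute null weights and null AMAS at all L
#' positions (zero where the weight is zero or mu does not exceed
#' theta). All `n_reps * L` null AMAS values are pooled, and for each
#' observed PAL position j,
#' `p_j = max(#(null AMAS > AMAS_j), 1) / (n_reps * L)`.
#' The attainable floor `1 / (n_reps * L)` is recorded; a p at the floor
#' is an upper bound (no exceedances observed), flagged in `$at_floor`.
#'
#' @param Amat The observed [mas_matrix()].
#' @param report The `pal_report` built from `Amat` (supplies theta
#'   percentile, AMAS and the PAL set).
#' @param null A `null_model` with positive `sigma`.
#' @param n_reps Number of sampling repetitions (default 100).
#' @param seed Integer seed.
#' @param positions Positions to report P-values for; defaults to
#'   `report$pal_amas`.
#' @return A `pvalue_set`: `positions`, `pvalues` in (0, 1], `at_floor`,
#'   `floor`, `n_reps`, `pool_size`.
#' @export
estimate_pvalues <- function(Amat, report, null, n_reps = 100L, seed = 1L,
                             positions = NULL) {
  stopifnot(inherits(Amat, "mas_matrix"), inherits(report, "pal_report"),
            inherits(null, "null_model"))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!(null$sigma > 0)) stop("null sigma must be positive")
  A <- Amat$A
  m <- nrow(A); L <- ncol(A)
  if (length(report$mu) != L) stop("report does not match the MAS matrix")
  if (is.null(positions)) positions <- report$pal_amas
  q <- report$theta_percentile

  obs_amas <- ifelse(is.na(report$amas), 0, report$amas)
  pool_size <- as.numeric(n_reps) * L
  # count exceedances against a sorted pool, one repetition at a time
  exceed <- numeric(length(positions))
  n_pos_null <- 0
  with_seed(seed, {
    for (rep_i in seq_len(n_reps)) {
      S <- matrix(abs(stats::rnorm(m * L, 0, null$sigma)), m, L)
      for (a in seq_len(m)) S[a, ] <- rank_match(S[a, ], A[a, ])
      null_mu <- colMeans(S)
      null_theta <- percentile_threshold(null_mu, q)
      null_w <- colMeans(S > null_theta)
      null_amas <- ifelse(null_mu > null_theta, null_w * null_mu, 0)
      n_pos_null <- n_pos_null + sum(null_amas > 0)
      if (length(positions) > 0L) {
        srt <- sort(null_amas)
        # exceedances of target value t: L - findInterval(t, sorted)
        exceed <- exceed + (L - findInterval(obs_amas[positions], srt))
      }
    }
  })
  p <- pmax(exceed, 1) / pool_size
  structure(
    list(positions = positions, pvalues = p,
         at_floor = exceed == 0, floor = 1 / pool_size,
         n_reps = as.integer(n_reps), pool_size = pool_size,
         n_positive_null = n_pos_null, sigma = null$sigma,
         seed = as.integer(seed)),
    class = "pvalue_set"
  )
}

#' @export
print.pvalue_set <- function(x, ...) {
  cat(sprintf("pvalue_set: %d position(s), %d reps, floor = %.3g\n",
              length(x$positions), x$n_reps, x$floor))
  if (length(x$positions) > 0L) {
    cat(sprintf("  min p = %.3g%s\n", min(x$pvalues),
                if (any(x$at_floor)) " (at floor; upper bound)" else ""))
  }
  invisible(x)
}

#' Write P-values (merged with PAL coordinates) as TSV + JSON
#' @param pv A `pvalue_set`.
#' @param g The [genotype_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pvalues <- function(pv, g, path) {
  tab <- data.frame(position = pv$positions,
                    id = g$variants$id[pv$positions],
                    chrom = g$variants$chrom[pv$positions],
                    bp = g$variants$bp[pv$positions],
                    p = pv$pvalues, at_floor = pv$at_floor)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sigma = pv$sigma, n_reps = pv$n_reps, pool_size = pv$pool_size,
         floor = pv$floor, seed = pv$seed),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
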