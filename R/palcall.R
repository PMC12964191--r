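#' Stack per-model MAS vectors into a MAS matrix
#'
#' @param mas_list List of `mas_vector`s of equal length and method.
#' @return A `mas_matrix`: `A` (m x L, rows summing to 1), `model_seeds`,
#'   `method`.
#' @export
mas_matrix <- function(mas_list) {
  stopifnot(length(mas_list) >= 1L,
            all(vapply(mas_list, inherits, logical(1), "mas_vector")))
  lens <- vapply(mas_list, function(m) length(m$values), integer(1))
  if (length(unique(lens)) != 1L) stop("MAS vectors differ in length")
  A <- do.call(rbind, lapply(mas_list, `[[`, "values"))
  structure(
    list(A = A,
         model_seeds = vapply(mas_list, function(m) as.integer(m$model_seed %||% NA_integer_), integer(1)),
         method = mas_list[[1]]$method),
    class = "mas_matrix"
  )
}

#' Percentile score threshold
#'
#' With N distinct values and percentile q, the threshold is the value
#' ranked `floor(N * (1 - q/100)) + 1` from the top, so that exactly
#' `floor(N * (1 - q/100))` values lie strictly above it. For the
#' genome-wide array size N = 290522 this leaves 29 positions above the
#' strict threshold (q = 99.99) and 145 above the relaxed one
#' (q = 99.95).
#'
#' @param values Numeric vector (length >= 1).
#' @param q Percentile in (0, 100).
#' @return The threshold value theta.
#' @export
percentile_threshold <- function(values, q) {
  if (q <= 0 || q >= 100) stop("percentile q must lie strictly in (0, 100)")
  n <- length(values)
  if (n < 1L) stop("empty value vector")
  k <- floor(n * (1 - q / 100))
  sort(values, decreasing = TRUE)[k + 1L]
}

#' Aggregate a MAS matrix into a PAL report
#'
#' Implements the multi-seed aggregation: the average MAS vector
#' `mu_j = mean_a A_aj`; a single threshold `theta` set at percentile `q`
#' of `mu` (by default; `theta_from = "pooled"` instead takes the
#' percentile of all m x L per-model values); occurrence weights
#' `w_j = (1/m) sum_a 1(A_aj > theta)`; the adjusted score
#' `AMAS_j = w_j * mu_j` for positions with `mu_j > theta`;
#' `PAL_AMAS = {j : AMAS_j > theta}` and
#' `PAL_Common = {j : A_aj > theta for all a}`. Strict inequalities are
#' used throughout, so `PAL_Common` is always a subset of `PAL_AMAS`.
#'
#' @param Amat A [mas_matrix()].
#' @param q Threshold percentile: 99.99 (strict) or 99.95 (relaxed), or
#'   any value in (0, 100).
#' @param theta_from `"mu"` (default) or `"pooled"`.
#' @return A `pal_report` with fields `mu`, `theta`, `theta_percentile`,
#'   `weights`, `amas` (length L; `NA` where `mu_j <= theta`),
#'   `pal_amas`, `pal_common` (integer position sets), `detected_by_model`
#'   (list of per-model exceedance sets), `m`.
#' @export
aggregate_mas <- function(Amat, q = 99.99, theta_from = c("mu", "pooled")) {
  stopifnot(inherits(Amat, "mas_matrix"))
  theta_from <- match.arg(theta_from)
  A <- Amat$A
  m <- nrow(A)
  mu <- colMeans(A)
  theta <- if (theta_from == "mu") {
    percentile_threshold(mu, q)
  } else {
    percentile_threshold(as.vector(A), q)
  }
  if (anyDuplicated(mu[mu == theta]) || sum(mu == theta) > 1L) {
    message("exact ties at theta fall below the strict threshold")
  }
  exceed <- A > theta
  w <- colMeans(exceed)
  amas <- ifelse(mu > theta, w * mu, NA_real_)
  pal_amas <- which(!is.na(amas) & amas > theta)
  pal_common <- which(colSums(exceed) == m)
  detected_by_model <- apply(exceed, 1L, which, simplify = FALSE)
  structure(
    list(mu = mu, theta = theta, theta_percentile = q,
         theta_from = theta_from, weights = w, amas = amas,
         pal_amas = pal_amas, pal_common = pal_common,
         detected_by_model = detected_by_model,
         m = m, method = Amat$method, model_seeds = Amat$model_seeds),
    class = "pal_report"
  )
}

#' @export
print.pal_report <- function(x, ...) {
  cat(sprintf("pal_report [%s]: L = %d, m = %d models, theta = %.3g (%.2f pct of %s)\n",
              x$method %||% "?", length(x$mu), x$m, x$theta,
              x$theta_percentile, x$theta_from))
  cat(sprintf("  PAL_AMAS: %d positions; PAL_Common: %d positions\n",
              length(x$pal_amas), length(x$pal_common)))
  if (!is.null(x$signals)) {
    cat(sprintf("  %d cross-model signal group(s)\n", length(x$signals)))
  }
  invisible(x)
}

#' Merge cross-model detections by LD
#'
#' Takes per-model detected position sets, forms their union, connects
#' positions whose absolute Pearson correlation exceeds `r_threshold`
#' (default 0.5) and returns the connected components (transitive
#' closure) as common signal groups. The representative of each group is
#' its highest-AMAS member (highest mean MAS when AMAS is unavailable).
#'
#' @param detected List of integer position vectors, one per model (or a
#'   single vector).
#' @param g The [genotype_matrix] used for correlations (whole cohort:
#'   cases and controls).
#' @param r_threshold Absolute-correlation edge threshold.
#' @param amas Optional numeric vector (length L) used to pick group
#'   representatives.
#' @return List of signal groups, each a list with `positions` (integer
#'   vector) and `representative`.
#' @export
clump_cross_model <- function(detected, g, r_threshold = 0.5, amas = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.list(detected)) detected <- list(detected)
  pos <- sort(unique(unlist(detected)))
  if (length(pos) == 0L) return(list())
  if (any(pos < 1L | pos > ncol(g$values))) stop("detected positions out of range")
  r <- ld_matrix(g, pos)
  dropped <- attr(r, "dropped")
  if (length(dropped) > 0L) {
    warning("zero-variance column(s) excluded from LD clumping: ",
            paste(dropped, collapse = ", "))
    keep <- !(pos %in% dropped)
    pos <- pos[keep]
    if (length(pos) == 0L) return(list())
    r <- r[keep, keep, drop = FALSE]
  }
  adj <- abs(r) > r_threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  lapply(split(pos, comp), function(p) {
    score <- if (is.null(amas)) rep(0, length(p)) else {
      s <- amas[p]
      s[is.na(s)] <- -Inf
      s
    }
    list(positions = unname(p), representative = unname(p[which.max(score)]))
  })
}

#' Clump detected SNPs into distance blocks
#'
#' Consecutive detected SNPs on the same chromosome at most `gap` base
#' pairs apart join one block; a chromosome change or a larger gap starts
#' a new block. Used to count signals at the locus level when evaluating
#' against causal positions.
#'
#' @param positions Integer column indices of detected SNPs.
#' @param g The [genotype_matrix] providing (chrom, bp).
#' @param gap Maximum intra-block gap in bp (default 100000).
#' @return List of blocks, each a list with `positions`, `chrom`,
#'   `bp_range`.
#' @export
block_clump_distance <- function(positions, g, gap = 1e5) {
  if (length(positions) == 0L) return(list())
  v <- g$variants[positions, , drop = FALSE]
  o <- order(v$chrom, v$bp)
  v <- v[o, , drop = FALSE]
  positions <- positions[o]
  new_block <- c(TRUE, v$chrom[-1] != v$chrom[-nrow(v)] |
                   diff(v$bp) > gap)
  bid <- cumsum(new_block)
  lapply(split(seq_along(positions), bid), function(ix) {
    list(positions = positions[ix],
         chrom = v$chrom[ix[1]],
         member_bps = v$bp[ix],
         bp_range = range(v$bp[ix]))
  })
}

#' Full PAL report table
#'
#' Adds LD-merged cross-model signals to an aggregated report and renders
#' a per-position table.
#'
#' @param report A `pal_report` from [aggregate_mas()].
#' @param g The [genotype_matrix].
#' @param r_threshold LD threshold for [clump_cross_model()].
#' @return The report with `signals` added.
#' @export
finalize_pal <- function(report, g, r_threshold = 0.5) {
  stopifnot(inherits(report, "pal_report"))
  report$signals <- clump_cross_model(report$detected_by_model, g,
                                      r_threshold = r_threshold,
                                      amas = report$amas)
  report
}

#' Write a PAL report as TSV + JSON summary
#'
#' @param report A `pal_report` (ideally after [finalize_pal()]).
#' @param g The [genotype_matrix].
#' @param path Output TSV path; a `.json` summary sidecar is added.
#' @param all_positions Write all L rows (default: only positions with
#'   `mu > theta`, any model detection, or membership in a signal group).
#' @return `path`, invisibly.
#' @export
write_pal_report <- function(report, g, path, all_positions = FALSE) {
  L <- length(report$mu)
  sig_id <- rep(NA_integer_, L)
  for (i in seq_along(report$signals)) {
    sig_id[report$signals[[i]]$positions] <- i
  }
  keep <- if (all_positions) seq_len(L) else {
    sort(unique(c(which(report$mu > report$theta),
                  unlist(report$detected_by_model),
                  which(!is.na(sig_id)))))
  }
  tab <- data.frame(
    position = keep,
    id = g$variants$id[keep], chrom = g$variants$chrom[keep],
    bp = g$variants$bp[keep],
    mu = report$mu[keep], w = report$weights[keep],
    amas = report$amas[keep],
    in_pal_amas = keep %in% report$pal_amas,
    in_pal_common = keep %in% report$pal_common,
    signal_group = sig_id[keep]
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(theta = report$theta, theta_percentile = report$theta_percentile,
         theta_from = report$theta_from, m = report$m,
         method = report$method, model_seeds = report$model_seeds,
         n_pal_amas = length(report$pal_amas),
         n_pal_common = length(report$pal_common),
         n_signals = length(report$signals %||% list())),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
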