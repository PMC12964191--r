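#' Per-SNP logistic-regression GWAS
#'
#' Fits one logistic model per SNP — `label ~ dosage + covariates` with
#' an intercept — and reports the Wald P-value of the dosage term. The
#' family-wise Bonferroni threshold `alpha / n_tested` is attached (all
#' attempted tests count in the denominator). SNPs with non-convergence
#' or complete separation are flagged and their P-value set to `NA`,
#' never silently zero.
#'
#' @param g A [genotype_matrix].
#' @param labels Binary 0/1 vector.
#' @param covariates Optional numeric matrix of row-aligned covariates
#'   (e.g. [pca_covariates()] scores).
#' @param alpha Family-wise significance level (default 0.05).
#' @return An `assoc_result` with a per-variant data.frame `table`
#'   (`id`, `chrom`, `bp`, `beta`, `se`, `p`, `flag`) and
#'   `bonferroni_threshold`.
#' @export
logistic_gwas <- function(g, labels, covariates = NULL, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n <- nrow(g$values)
  if (length(labels) != n) stop("labels must align with genotype rows")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must be row-aligned with genotypes")
  }
  L <- ncol(g$values)
  y <- as.numeric(labels)
  base <- cbind(Intercept = rep(1, n), covariates)
  beta <- se <- p <- rep(NA_real_, L)
  flag <- character(L)
  for (j in seq_len(L)) {
    x <- as.numeric(g$values[, j])
    if (stats::var(x) == 0) {
      flag[j] <- "zero-variance"
      next
    }
    X <- cbind(dosage = x, base)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                      control = stats::glm.control(
                                        epsilon = 1e-12, maxit = 50))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      flag[j] <- "non-convergence"
      next
    }
    mu <- fit$fitted.values
    if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      flag[j] <- "separation"
      next
    }
    # Wald: covariance from the weighted information matrix
    W <- mu * (1 - mu)
    info <- crossprod(X * sqrt(W))
    cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(cov)) {
      flag[j] <- "singular-information"
      next
    }
    beta[j] <- fit$coefficients[1L]
    se[j] <- sqrt(cov[1L, 1L])
    z <- beta[j] / se[j]
    p[j] <- 2 * stats::pnorm(-abs(z))
  }
  n_flagged <- sum(nzchar(flag))
  if (n_flagged > 0L) {
    message(n_flagged, " SNP(s) flagged (no P-value): ",
            paste(utils::head(g$variants$id[nzchar(flag)], 5L), collapse = ", "),
            if (n_flagged > 5L) ", ..." else "")
  }
  structure(
    list(table = data.frame(id = g$variants$id, chrom = g$variants$chrom,
                            bp = g$variants$bp, beta = beta, se = se, p = p,
                            flag = flag, stringsAsFactors = FALSE),
         n_tested = L, alpha = alpha,
         covariate_names = colnames(covariates),
         bonferroni_threshold = alpha / L),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result: %d SNPs tested, Bonferroni threshold %.3g\n",
              x$n_tested, x$bonferroni_threshold))
  cat(sprintf("  %d significant at Bonferroni\n",
              sum(x$table$p < x$bonferroni_threshold, na.rm = TRUE)))
  invisible(x)
}

#' Family-wise Bonferroni threshold
#'
#' @param alpha Family-wise significance level.
#' @param n_tested Number of tests (all attempted tests count).
#' @return `alpha / n_tested`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tested) {
  stopifnot(alpha > 0, n_tested >= 1)
  alpha / n_tested
}

#' Import externally produced per-SNP P-values
#'
#' Generic path for consuming association results from external tools as
#' TSV with columns `variant_id` and `p`.
#'
#' @param path TSV file.
#' @param g A [genotype_matrix] to align against.
#' @return An `assoc_result` (beta/se `NA`).
#' @export
import_association <- function(path, g) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "p") %in% names(tab))) {
    stop("expected TSV columns 'variant_id' and 'p'")
  }
  idx <- match(g$variants$id, tab$variant_id)
  structure(
    list(table = data.frame(id = g$variants$id, chrom = g$variants$chrom,
                            bp = g$variants$bp, beta = NA_real_, se = NA_real_,
                            p = tab$p[idx], flag = "",
                            stringsAsFactors = FALSE),
         n_tested = sum(!is.na(idx)), alpha = 0.05,
         bonferroni_threshold = 0.05 / max(1L, sum(!is.na(idx)))),
    class = "assoc_result"
  )
}

#' Label detected blocks as true or false positives
#'
#' A block is a true positive if one or more of its member SNPs lies
#' within `window` bp (closed interval, same chromosome) of any causal
#' position; otherwise it is a false positive. Each block is counted
#' once, which avoids inflating TP counts when several correlated SNPs
#' tag the same causal locus.
#'
#' @param blocks Block list from [block_clump_distance()].
#' @param causal Data.frame of causal positions with columns `chrom`,
#'   `bp` (and optionally `position`, `class`).
#' @param window Proximity window in bp (default 100000).
#' @return A `detection_eval` with `tp`, `fp`, `blocks`,
#'   `block_is_tp`, `causal_detected` (logical per causal row) and the
#'   inputs.
#' @export
label_detections <- function(blocks, causal, window = 1e5) {
  causal <- as.data.frame(causal, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "bp") %in% names(causal)))
  block_is_tp <- logical(length(blocks))
  causal_detected <- logical(nrow(causal))
  # evaluate each block against every causal position (order-invariant)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (is.null(blk$member_bps)) {
      stop("blocks must carry member_bps (see block_clump_distance())")
    }
    for (ci in which(causal$chrom == blk$chrom)) {
      if (any(abs(blk$member_bps - causal$bp[ci]) <= window)) {
        block_is_tp[b] <- TRUE
        causal_detected[ci] <- TRUE
      }
    }
  }
  structure(
    list(blocks = blocks, block_is_tp = block_is_tp,
         tp = sum(block_is_tp), fp = sum(!block_is_tp),
         causal = causal, causal_detected = causal_detected,
         window = window),
    class = "detection_eval"
  )
}

#' Precision and recall of a detection evaluation
#'
#' Precision is `tp / (tp + fp)` over blocks (`NA` when there are no
#' detections); recall is the fraction of causal positions lying within
#' the window of any detected block (a causal position covered by several
#' blocks counts once).
#'
#' @param eval A `detection_eval` from [label_detections()].
#' @param n_causal Recall denominator; defaults to the number of causal
#'   rows in the evaluation.
#' @return List with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
precision_recall <- function(eval, n_causal = NULL) {
  stopifnot(inherits(eval, "detection_eval"))
  if (is.null(n_causal)) n_causal <- nrow(eval$causal)
  n_det <- eval$tp + eval$fp
  list(
    precision = if (n_det > 0) eval$tp / n_det else NA_real_,
    recall = if (n_causal > 0) sum(eval$causal_detected) / n_causal else NA_real_,
    tp = eval$tp, fp = eval$fp,
    fn = n_causal - sum(eval$causal_detected)
  )
}

#' Detected-causal breakdown by effect type
#'
#' Attributes each detected causal position to its effect class and
#' reports per-class counts plus the dominant/recessive versus
#' interactive split.
#'
#' @param eval A `detection_eval` whose `causal` table has a `class`
#'   column (from [causal_table()]).
#' @return List with `per_class` (named counts) and `split`
#'   (`dominant_recessive` vs `interactive`).
#' @export
effect_type_breakdown <- function(eval) {
  stopifnot(inherits(eval, "detection_eval"))
  if (!"class" %in% names(eval$causal)) {
    stop("causal table lacks a 'class' column; build it with causal_table()")
  }
  det <- eval$causal$class[eval$causal_detected]
  lv <- c("dominant", "recessive", "two-way", "three-way")
  per_class <- table(factor(det, levels = lv))
  list(per_class = c(per_class),
       split = c(dominant_recessive = sum(per_class[c("dominant", "recessive")]),
                 interactive = sum(per_class[c("two-way", "three-way")])))
}

#' Causal-position table for evaluation
#'
#' Joins an effect specification with variant coordinates.
#'
#' @param e An `effect_spec`.
#' @param g The [genotype_matrix] it was assigned on.
#' @return Data.frame with `position`, `chrom`, `bp`, `class`.
#' @export
causal_table <- function(e, g) {
  cc <- causal_classes(e)
  cc$chrom <- g$variants$chrom[cc$position]
  cc$bp <- g$variants$bp[cc$position]
  cc
}

#' Evaluate a detected-position set against causal positions
#'
#' Convenience wrapper: distance-clumps the detections into blocks,
#' labels TP/FP and computes precision/recall.
#'
#' @param positions Detected SNP column indices.
#' @param e The `effect_spec` holding the ground truth.
#' @param g The [genotype_matrix].
#' @param window Proximity window in bp.
#' @param gap Block-clumping gap in bp.
#' @return List with `eval` (a `detection_eval`), `metrics`
#'   (precision/recall) and `breakdown`.
#' @export
evaluate_detections <- function(positions, e, g, window = 1e5, gap = 1e5) {
  blocks <- block_clump_distance(positions, g, gap = gap)
  ev <- label_detections(blocks, causal_table(e, g), window = window)
  list(eval = ev, metrics = precision_recall(ev, n_causal = e$n_causal),
       breakdown = effect_type_breakdown(ev))
}
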