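#' Saliency-map attributions
#'
#' The saliency score of feature j for input x is the absolute gradient
#' of the model output with respect to that input coordinate,
#' `SM_j(x) = |df(x)/dx_j|`. All dropout layers are inactive during
#' attribution, so repeated calls are deterministic.
#'
#' @param model A trained `palnn_model`.
#' @param x Input batch: numeric matrix (n_samples x L), a vector, or a
#'   [genotype_matrix] (typically the case samples only).
#' @return An `attribution_scores` object: non-negative `scores`
#'   (n_samples x L), `method = "SM"`.
#' @export
saliency <- function(model, x) {
  X <- as_input_matrix(model, x)
  new_attribution(abs(mlp_input_gradient(model, X)), "SM")
}

#' Integrated-gradients attributions
#'
#' Integrates the output gradient along the straight path from a baseline
#' x' to the input x:
#' `IG_j(x) = (x_j - x'_j) * Integral_0^1 df(x' + a(x - x'))/dx_j da`,
#' approximated by an `n_steps` midpoint Riemann sum; absolute values are
#' taken afterwards. The default baseline is the zero vector — under the
#' symmetric -1/0/1 genotype encoding this is an all-heterozygous genome
#' with no preference for either allele. For purely linear models the
#' closed form `|w_j x_j|` is recovered exactly for any number of steps.
#'
#' @inheritParams saliency
#' @param baseline Baseline vector (length L) or matrix conformable with
#'   `x`; default zeros.
#' @param n_steps Number of Riemann steps (default 50).
#' @return An `attribution_scores` object (`method = "IG"`). The signed
#'   sums before taking absolute values are available as attribute
#'   `"completeness"` for diagnostics.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, n_steps = 50L) {
  X <- as_input_matrix(model, x)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (is.null(baseline)) {
    Xp <- matrix(0, nrow(X), ncol(X))
  } else {
    Xp <- if (is.vector(baseline)) {
      matrix(baseline, nrow(X), ncol(X), byrow = TRUE)
    } else {
      as.matrix(baseline)
    }
    if (!all(dim(Xp) == dim(X))) stop("baseline does not conform with x")
  }
  diff <- X - Xp
  acc <- matrix(0, nrow(X), ncol(X))
  for (s in seq_len(n_steps)) {
    alpha <- (s - 0.5) / n_steps
    acc <- acc + mlp_input_gradient(model, Xp + alpha * diff)
  }
  signed <- diff * acc / n_steps
  out <- new_attribution(abs(signed), "IG")
  attr(out, "completeness") <- rowSums(signed)
  attr(out, "n_steps") <- as.integer(n_steps)
  out
}

#' Permutation-importance attributions
#'
#' Measures, for each feature j, the absolute change in the model output
#' when that feature is perturbed: `PM_j(x) = |f(x) - f(x^(j))|`. The
#' change in prediction (not in a performance metric) is used because
#' each SNP is expected to contribute only marginally to the output.
#' Two replacement modes are provided:
#' \describe{
#'   \item{`"permute-samples"`}{coordinate j is replaced by feature j's
#'     value in a randomly drawn other sample from `reference`
#'     (preserves the feature's marginal distribution);}
#'   \item{`"random-feature"`}{coordinate j is replaced by the sample's
#'     own value at a uniformly drawn other position.}
#' }
#'
#' @inheritParams saliency
#' @param mode Replacement mode; default `"permute-samples"`.
#' @param reference Reference sample pool (matrix n_ref x L) for
#'   `"permute-samples"`; defaults to `x` itself when it has more than
#'   one row.
#' @param seed Integer seed for the replacement draws.
#' @return An `attribution_scores` object (`method = "PM"`).
#' @export
permutation_importance <- function(model, x,
                                   mode = c("permute-samples", "random-feature"),
                                   reference = NULL, seed = 1L) {
  mode <- match.arg(mode)
  X <- as_input_matrix(model, x)
  n <- nrow(X); L <- ncol(X)
  if (mode == "permute-samples") {
    R <- if (is.null(reference)) X else as_input_matrix(model, reference)
    if (nrow(R) < 2L) stop("permute-samples mode needs a reference pool with >= 2 samples")
  }
  f0 <- mlp_forward(model, X)
  scores <- matrix(0, n, L)
  with_seed(seed, {
    for (i in seq_len(n)) {
      repl <- if (mode == "permute-samples") {
        donors <- sample.int(nrow(R), L, replace = TRUE)
        R[cbind(donors, seq_len(L))]
      } else {
        other <- sample.int(L - 1L, L, replace = TRUE)
        other <- other + (other >= seq_len(L))  # skip position j itself
        X[i, other]
      }
      scores[i, ] <- abs(perturbed_outputs(model, X[i, ], repl) - f0[i])
    }
  })
  out <- new_attribution(scores, "PM")
  attr(out, "mode") <- mode
  out
}

# Outputs f(x^(j)) for all j at once: only coordinate j changes, so the
# first-layer pre-activation is updated incrementally (rank-1 per
# feature) and the small upper layers are re-run for all L variants.
perturbed_outputs <- function(model, x, repl) {
  cfg <- model$config
  L <- length(x)
  z1 <- drop(crossprod(model$W1, x)) + model$b1        # h1
  delta <- repl - x                                    # L
  Z1 <- matrix(z1, nrow = L, ncol = length(z1), byrow = TRUE) +
    delta * model$W1                                   # L x h1
  A1 <- act_fun(cfg$activations[1])(Z1)
  Z2 <- sweep(A1 %*% model$W2, 2L, model$b2, "+")
  A2 <- act_fun(cfg$activations[2])(Z2)
  z3 <- drop(A2 %*% model$W3) + model$b3
  if (cfg$output == "sigmoid") stats::plogis(z3) else z3
}

new_attribution <- function(scores, method) {
  stopifnot(all(scores >= 0))
  structure(list(method = method, scores = scores, normalized = FALSE),
            class = "attribution_scores")
}

#' @export
print.attribution_scores <- function(x, ...) {
  cat(sprintf("attribution_scores [%s]: %d samples x %d positions%s\n",
              x$method, nrow(x$scores), ncol(x$scores),
              if (x$normalized) " (L1-normalized)" else ""))
  invisible(x)
}

#' Mean attribution score (MAS)
#'
#' Each sample's attribution row is divided by its L1 norm — turning raw
#' scores into per-sample contribution fractions — and the normalised
#' rows are averaged positionwise over samples. The resulting MAS vector
#' sums to 1.
#'
#' @param scores An `attribution_scores` object (non-negative, at least
#'   one sample; an all-zero row signals a degenerate attribution).
#' @param model_seed Optional seed of the model that produced the scores
#'   (recorded for aggregation bookkeeping).
#' @param on_zero What to do with all-zero sample rows, which cannot be
#'   L1-normalised: `"error"` (default) or `"drop"` (remove with a
#'   warning; small ReLU networks can leave a sample's entire gradient
#'   path dead).
#' @return A `mas_vector`: `values` (length L, non-negative, summing to
#'   1), `method`, `n_samples_averaged`, `model_seed`.
#' @export
compute_mas <- function(scores, model_seed = NA_integer_,
                        on_zero = c("error", "drop")) {
  stopifnot(inherits(scores, "attribution_scores"))
  on_zero <- match.arg(on_zero)
  s <- scores$scores
  if (nrow(s) < 1L) stop("at least one sample required")
  norms <- rowSums(s)
  if (any(norms == 0)) {
    if (on_zero == "error" || all(norms == 0)) {
      stop("degenerate attribution: sample row(s) ",
           paste(utils::head(which(norms == 0), 3L), collapse = ", "),
           " are all zero")
    }
    warning("dropped ", sum(norms == 0),
            " all-zero attribution row(s) before L1 normalization")
    s <- s[norms > 0, , drop = FALSE]
    norms <- norms[norms > 0]
  }
  normalized <- s / norms
  structure(
    list(values = colMeans(normalized), method = scores$method,
         n_samples_averaged = nrow(s), model_seed = model_seed),
    class = "mas_vector"
  )
}

#' Per-model MAS in one call
#'
#' Runs the requested attribution method on the case samples and reduces
#' to a MAS vector.
#'
#' @param model A trained `palnn_model`.
#' @param g A [genotype_matrix] or numeric matrix.
#' @param labels Binary labels; attribution uses the case samples
#'   (`labels == 1`) per default.
#' @param method `"ig"`, `"sm"` or `"pm"`.
#' @param include_controls Attribute over all samples instead of cases
#'   only (diagnostic).
#' @param n_steps Riemann steps for IG.
#' @param pm_subsample Optional cap on the number of case samples used
#'   for the (costly) permutation method; subsampling is seeded and the
#'   size recorded on the result.
#' @param seed Seed for PM draws / subsampling.
#' @return A `mas_vector`.
#' @export
model_mas <- function(model, g, labels, method = c("ig", "sm", "pm"),
                      include_controls = FALSE, n_steps = 50L,
                      pm_subsample = NULL, seed = 1L) {
  method <- match.arg(method)
  X <- if (inherits(g, "genotype_matrix")) g$values else as.matrix(g)
  storage.mode(X) <- "double"
  rows <- if (include_controls) seq_len(nrow(X)) else which(labels == 1L)
  if (length(rows) == 0L) stop("no case samples to attribute")
  Xc <- X[rows, , drop = FALSE]
  scores <- switch(method,
    sm = saliency(model, Xc),
    ig = integrated_gradients(model, Xc, n_steps = n_steps),
    pm = {
      if (!is.null(pm_subsample) && pm_subsample < nrow(Xc)) {
        keep <- with_seed(seed, sample.int(nrow(Xc), pm_subsample))
        Xc <- Xc[keep, , drop = FALSE]
      }
      permutation_importance(model, Xc, seed = seed)
    })
  mas <- compute_mas(scores, model_seed = model$config$seed, on_zero = "drop")
  mas$method <- toupper(method)
  mas
}

#' MAS vectors for a whole ensemble
#'
#' Applies [model_mas()] to each model. Very narrow networks can end up
#' with *every* case sample on a dead gradient path, leaving no
#' attribution mass at all; with `drop_degenerate = TRUE` such models are
#' removed from the ensemble with a warning (recorded in the
#' `"n_dropped_models"` attribute) instead of aborting the run.
#'
#' @param models List of trained `palnn_model`s.
#' @param g,labels,method,... Passed to [model_mas()].
#' @param drop_degenerate Drop models with fully degenerate attributions.
#' @return List of `mas_vector`s.
#' @export
ensemble_mas <- function(models, g, labels, method = "ig",
                         drop_degenerate = FALSE, ...) {
  out <- lapply(models, function(m) {
    tryCatch(model_mas(m, g, labels, method = method, ...),
             error = function(e) {
               if (drop_degenerate && grepl("degenerate", conditionMessage(e))) {
                 warning("dropping model (seed ", m$config$seed,
                         ") with fully degenerate attributions",
                         call. = FALSE)
                 NULL
               } else {
                 stop(e)
               }
             })
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L) stop("every model in the ensemble is degenerate")
  attr(out, "n_dropped_models") <- dropped
  out
}

#' @export
print.mas_vector <- function(x, ...) {
  cat(sprintf("mas_vector [%s]: L = %d, averaged over %d samples (sum = %.6f)\n",
              x$method, length(x$values), x$n_samples_averaged,
              sum(x$values)))
  invisible(x)
}

#' Write a MAS vector as TSV with JSON metadata
#' @param mas A `mas_vector`.
#' @param g The [genotype_matrix] providing variant coordinates.
#' @param path Output TSV path (a `.json` sidecar is added).
#' @return `path`, invisibly.
#' @export
write_mas <- function(mas, g, path) {
  tab <- data.frame(id = g$variants$id, chrom = g$variants$chrom,
                    bp = g$variants$bp, mas = mas$values)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(method = mas$method, model_seed = mas$model_seed,
         n_samples_averaged = mas$n_samples_averaged),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
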