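#' Assign causal effect positions and weights
#'
#' Draws `n_causal` positions uniformly without replacement genome-wide
#' and partitions them into four effect classes in the fixed ratio
#' 5:5:4:6 — dominant, recessive, two-way interaction members and
#' three-way interaction members — so that dominant/recessive and
#' interactive classes contain equal numbers of causal SNPs. Interaction
#' members are shuffled and chunked consecutively into disjoint pairs and
#' triplets. Every effect (per dominant/recessive position, per pair, per
#' triplet) receives a weight drawn from the standard normal.
#'
#' @param g A [genotype_matrix].
#' @param n_causal Total causal SNPs; must be divisible by 20 so the
#'   5:5:4:6 ratio yields integer class sizes.
#' @param seed Integer seed.
#' @param ratio Effect-class ratio over (dominant, recessive, two-way
#'   members, three-way members); default `c(5, 5, 4, 6)`.
#' @return An object of class `effect_spec` with fields `dominant`,
#'   `recessive`, `pairs` (2-column matrix), `triplets` (3-column matrix),
#'   `beta_single` (named by position), `beta_pair`, `beta_triplet`.
#' @export
assign_effects <- function(g, n_causal, seed = 1L, ratio = c(5, 5, 4, 6)) {
  stopifnot(inherits(g, "genotype_matrix"))
  L <- ncol(g$values)
  total <- sum(ratio)
  counts <- n_causal * ratio / total
  if (any(counts != floor(counts))) {
    stop("n_causal (", n_causal, ") must be divisible by ", total,
         " for the ", paste(ratio, collapse = ":"), " effect-class ratio")
  }
  if (counts[3] %% 2 != 0 || counts[4] %% 3 != 0) {
    stop("interaction member counts must split into whole pairs/triplets")
  }
  if (n_causal > L) stop("n_causal exceeds the number of positions (", L, ")")
  counts <- as.integer(counts)

  with_seed(seed, {
    idx <- sample.int(L, n_causal)
    dominant <- sort(idx[seq_len(counts[1])])
    recessive <- sort(idx[counts[1] + seq_len(counts[2])])
    pair_members <- idx[counts[1] + counts[2] + seq_len(counts[3])]
    trip_members <- idx[counts[1] + counts[2] + counts[3] + seq_len(counts[4])]
    pairs <- matrix(sample(pair_members), ncol = 2L, byrow = TRUE)
    triplets <- matrix(sample(trip_members), ncol = 3L, byrow = TRUE)
    beta_single <- stats::rnorm(counts[1] + counts[2])
    names(beta_single) <- c(dominant, recessive)
    spec <- structure(
      list(dominant = dominant, recessive = recessive,
           pairs = pairs, triplets = triplets,
           beta_single = beta_single,
           beta_pair = stats::rnorm(nrow(pairs)),
           beta_triplet = stats::rnorm(nrow(triplets)),
           n_causal = as.integer(n_causal), seed = as.integer(seed)),
      class = "effect_spec"
    )
    validate_effect_spec(spec)
    spec
  })
}

validate_effect_spec <- function(e) {
  all_idx <- causal_positions(e)
  if (anyDuplicated(all_idx)) stop("effect classes must be disjoint")
  if (length(all_idx) != e$n_causal) {
    stop("class sizes do not sum to n_causal")
  }
  invisible(e)
}

#' All causal positions of an effect specification
#' @param e An `effect_spec`.
#' @return Integer vector of position indices.
#' @export
causal_positions <- function(e) {
  c(e$dominant, e$recessive, as.vector(e$pairs), as.vector(e$triplets))
}

# Per-position effect class, for detection breakdowns.
causal_classes <- function(e) {
  data.frame(
    position = causal_positions(e),
    class = rep(c("dominant", "recessive", "two-way", "three-way"),
                c(length(e$dominant), length(e$recessive),
                  length(e$pairs), length(e$triplets))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("effect_spec:", x$n_causal, "causal SNPs\n")
  cat("  dominant:", length(x$dominant),
      " recessive:", length(x$recessive),
      " pairs:", nrow(x$pairs),
      " triplets:", nrow(x$triplets), "\n")
  invisible(x)
}

#' Write an effect specification as JSON
#' @param e An `effect_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_spec <- function(e, path) {
  jsonlite::write_json(
    list(dominant = e$dominant, recessive = e$recessive,
         pairs = e$pairs, triplets = e$triplets,
         beta_single = as.list(e$beta_single),
         beta_pair = e$beta_pair, beta_triplet = e$beta_triplet,
         n_causal = e$n_causal, seed = e$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an effect specification from JSON
#' @param path JSON path written by [write_effect_spec()].
#' @return An `effect_spec`.
#' @export
read_effect_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(
    list(dominant = as.integer(x$dominant), recessive = as.integer(x$recessive),
         pairs = matrix(as.integer(x$pairs), ncol = 2L),
         triplets = matrix(as.integer(x$triplets), ncol = 3L),
         beta_single = unlist(x$beta_single),
         beta_pair = as.numeric(x$beta_pair),
         beta_triplet = as.numeric(x$beta_triplet),
         n_causal = as.integer(x$n_causal), seed = as.integer(x$seed)),
    class = "effect_spec"
  )
  validate_effect_spec(spec)
  spec
}
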