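#' Genotype matrix container
#'
#' Holds an individuals-by-positions matrix of SNP-array genotypes in the
#' symmetric ternary encoding: -1 (homozygous reference, AA), 0
#' (heterozygous, AB) and 1 (homozygous alternate, BB). The symmetric
#' coding gives either allele equal weight under symmetric (e.g. Kaiming
#' uniform) network initialisation; it is the alt-allele dosage 0/1/2
#' shifted down by one.
#'
#' @param values Integer matrix (n_individuals x n_positions) with entries
#'   in \{-1, 0, 1\}.
#' @param variants `data.frame` with columns `chrom` (character), `bp`
#'   (1-based integer position) and `id` (character), one row per column
#'   of `values`, sorted by (chrom, bp) with `bp` unique within chromosome.
#' @param sample_ids Character vector, one per row of `values`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, variants, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!all(values %in% c(-1L, 0L, 1L))) {
    bad <- which(!(values %in% c(-1L, 0L, 1L)))[1L]
    stop("genotype values must be -1, 0 or 1; offending entry at index ", bad)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "bp", "id") %in% names(variants)))
  variants$chrom <- as.character(variants$chrom)
  variants$bp <- as.integer(variants$bp)
  variants$id <- as.character(variants$id)
  if (nrow(variants) != ncol(values)) {
    stop("variants (", nrow(variants), ") must match genotype columns (",
         ncol(values), ")")
  }
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids must match genotype rows")
  }
  if (any(variants$bp < 1L)) stop("bp positions must be >= 1 (1-based)")
  o <- order(variants$chrom, variants$bp)
  if (is.unsorted(o)) stop("variants must be sorted by (chrom, bp)")
  if (anyDuplicated(variants[c("chrom", "bp")])) {
    stop("bp positions must be unique within a chromosome")
  }
  rownames(values) <- sample_ids
  colnames(values) <- variants$id
  structure(
    list(values = values, variants = variants,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "individuals x",
      ncol(x$values), "positions\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  af <- mean(x$values + 1L) / 2
  cat(sprintf("  mean alt-allele frequency: %.3f\n", af))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

n_positions <- function(g) ncol(g$values)
n_individuals <- function(g) nrow(g$values)
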