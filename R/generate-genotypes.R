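#' Generate synthetic SNP-array genotypes with block-wise LD
#'
#' Simulates a ternary genotype matrix emulating the salient features of
#' array data: a realistic minor-allele-frequency spectrum, and linkage
#' disequilibrium that is strong within local blocks and absent between
#' blocks. Positions are grouped into consecutive blocks of `block_size`
#' SNPs; for each block a small pool of founder haplotypes is drawn, and
#' every individual samples two haplotypes per block (with replacement)
#' with a per-site mutation probability. Sharing founders induces
#' decaying within-block correlation, while independent pools across
#' blocks give near-zero cross-block correlation.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_positions Number of SNPs (>= 1).
#' @param block_size SNPs per LD block (default 10).
#' @param haplotype_pool Founder haplotypes per block (default 8). Smaller
#'   pools give stronger LD.
#' @param maf_range Length-2 numeric interval inside (0, 0.5] from which
#'   per-site allele frequencies are drawn uniformly.
#' @param bp_spacing Base-pair distance between consecutive SNPs
#'   (default 5000, matching typical genome-wide array density where
#'   +/-100 kb is roughly +/-20 SNPs).
#' @param mutation_p Per-site probability of flipping an inherited allele
#'   (default 0.01); keeps columns from being exact copies of founders.
#' @param chrom Chromosome label for all generated variants (default "1").
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @return A [genotype_matrix].
#' @export
generate_genotypes <- function(n_individuals, n_positions,
                               block_size = 10L, haplotype_pool = 8L,
                               maf_range = c(0.05, 0.5),
                               bp_spacing = 5000L, mutation_p = 0.01,
                               chrom = "1", seed = 1L) {
  if (n_individuals < 2L || n_positions < 1L) {
    stop("n_individuals must be >= 2 and n_positions >= 1")
  }
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be a non-empty interval inside (0, 0.5]")
  }
  stopifnot(block_size >= 1L, haplotype_pool >= 1L, bp_spacing >= 1L)

  values <- with_seed(seed, {
    out <- matrix(0L, n_individuals, n_positions)
    starts <- seq.int(1L, n_positions, by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1L, n_positions)
      w <- e - s + 1L
      freqs <- runif(w, maf_range[1], maf_range[2])
      # founder haplotypes: haplotype_pool x w binary matrix
      founders <- matrix(rbinom(haplotype_pool * w, 1L, rep(freqs, each = haplotype_pool)),
                         nrow = haplotype_pool, ncol = w)
      h1 <- founders[sample.int(haplotype_pool, n_individuals, replace = TRUE), ,
                     drop = FALSE]
      h2 <- founders[sample.int(haplotype_pool, n_individuals, replace = TRUE), ,
                     drop = FALSE]
      if (mutation_p > 0) {
        flip1 <- matrix(rbinom(length(h1), 1L, mutation_p), nrow = n_individuals)
        flip2 <- matrix(rbinom(length(h2), 1L, mutation_p), nrow = n_individuals)
        h1 <- abs(h1 - flip1)
        h2 <- abs(h2 - flip2)
      }
      out[, s:e] <- h1 + h2 - 1L
    }
    out
  })

  bp <- seq.int(1L, by = as.integer(bp_spacing), length.out = n_positions)
  variants <- data.frame(
    chrom = chrom,
    bp = bp,
    id = sprintf("snp_%s_%d", chrom, bp),
    stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("ind_%0*d", nchar(n_individuals), seq_len(n_individuals))
  g <- genotype_matrix(values, variants, sample_ids)
  attr(g, "generator") <- list(
    n_individuals = n_individuals, n_positions = n_positions,
    block_size = block_size, haplotype_pool = haplotype_pool,
    maf_range = maf_range, bp_spacing = bp_spacing,
    mutation_p = mutation_p, chrom = chrom, seed = seed
  )
  g
}
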