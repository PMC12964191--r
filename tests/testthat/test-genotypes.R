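test_that("generated genotypes respect the ternary domain and dimensions", {
  g <- generate_genotypes(100, 500, block_size = 10, haplotype_pool = 8,
                          maf_range = c(0.05, 0.5), bp_spacing = 5000,
                          seed = 1)
  expect_equal(dim(g$values), c(100L, 500L))
  expect_true(all(g$values %in% c(-1L, 0L, 1L)))
  expect_equal(nrow(g$variants), 500L)
  expect_equal(diff(g$variants$bp), rep(5000L, 499L))
  # reproducibility
  g2 <- generate_genotypes(100, 500, block_size = 10, haplotype_pool = 8,
                           maf_range = c(0.05, 0.5), bp_spacing = 5000,
                           seed = 1)
  expect_identical(g$values, g2$values)
})

test_that("a degenerate maf_range forces the allele frequency", {
  g <- generate_genotypes(400, 50, maf_range = c(0.5, 0.5), mutation_p = 0,
                          haplotype_pool = 1000, seed = 2)
  af <- colMeans(g$values + 1L) / 2
  # two sampling layers: founder-pool frequency (1000 haplotypes) plus
  # 2n = 800 draws from the pool
  expect_true(all(abs(af - 0.5) < 6 * sqrt(0.25 / 800 + 0.25 / 1000)))
  expect_lt(abs(mean(af) - 0.5), 0.02)
})

test_that("within-block LD exceeds cross-block LD", {
  g <- generate_genotypes(2000, 1000, block_size = 10, haplotype_pool = 8,
                          seed = 3)
  # adjacent same-block pairs vs adjacent cross-block pairs
  same_block <- which(seq_len(999) %% 10 != 0)
  cross_block <- which(seq_len(999) %% 10 == 0)
  r_of <- function(i) suppressWarnings(
    abs(stats::cor(g$values[, i], g$values[, i + 1])))
  r_same <- mean(vapply(same_block, r_of, numeric(1)), na.rm = TRUE)
  r_cross <- mean(vapply(cross_block, r_of, numeric(1)), na.rm = TRUE)
  expect_gt(r_same, r_cross)
  expect_gt(r_same, 0.2)
  expect_lt(r_cross, 0.1)
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_genotypes(1, 10), "n_individuals")
  expect_error(generate_genotypes(10, 10, maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(generate_genotypes(10, 10, maf_range = c(0, 0.5)), "maf_range")
})

test_that("genotype_matrix enforces its invariants", {
  expect_error(toy_genotypes(matrix(c(0, 2), 1, 2)), "-1, 0 or 1")
  vals <- matrix(0L, 2, 2)
  expect_error(
    genotype_matrix(vals, data.frame(chrom = "1", bp = c(5L, 5L),
                                     id = c("a", "b")), c("s1", "s2")),
    "unique")
  expect_error(
    genotype_matrix(vals, data.frame(chrom = "1", bp = c(1L, 2L),
                                     id = c("a", "b")), "s1"),
    "sample_ids")
})

test_that("traw round-trips losslessly and maps dosage 0/1/2 to -1/0/1", {
  g <- generate_genotypes(20, 15, seed = 4)
  path <- withr::local_tempfile(fileext = ".traw")
  write_genotypes(g, path, "traw")
  g2 <- read_genotypes(path, "traw")
  expect_identical(g$values, g2$values)
  expect_equal(g$variants, g2$variants)
  expect_identical(g$sample_ids, g2$sample_ids)
  # dosage encoding: write a minimal .traw by hand
  p2 <- withr::local_tempfile(fileext = ".traw")
  writeLines(c("CHR\tSNP\t(C)M\tPOS\tCOUNTED\tALT\ts1\ts2\ts3",
               "1\trs1\t0\t100\tB\tA\t0\t1\t2"), p2)
  g3 <- read_genotypes(p2)  # format auto-detected
  expect_identical(as.vector(g3$values), c(-1L, 0L, 1L))
})

test_that("missing genotypes are rejected with variant and sample named", {
  p <- withr::local_tempfile(fileext = ".traw")
  writeLines(c("CHR\tSNP\t(C)M\tPOS\tCOUNTED\tALT\ts1\ts2",
               "1\trs77\t0\t100\t B\tA\t0\tNA"), p)
  expect_error(read_genotypes(p, "traw"), "rs77.*s2")
})

test_that("VCF writing and reading round-trip", {
  g <- generate_genotypes(12, 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, path, "vcf")
  g2 <- read_genotypes(path, "vcf")
  expect_identical(unname(g$values), unname(g2$values))
  expect_equal(g$variants$bp, g2$variants$bp)
  expect_identical(g$sample_ids, g2$sample_ids)
})

test_that("multi-allelic VCF records are rejected by name", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trs9\tA\tC,T\t.\tPASS\t.\tGT\t0/1"), path)
  expect_error(read_genotypes(path, "vcf"), "non-biallelic")
})

test_that("compute_ld matches Pearson correlation and is symmetric", {
  g <- toy_genotypes(cbind(c(-1, 0, 1, 1, -1), c(-1, 0, 1, 1, -1),
                           c(1, 0, -1, -1, 1), c(0, 1, -1, 0, 1)))
  expect_equal(compute_ld(g, 1, 2), 1)
  expect_equal(compute_ld(g, 1, 3), -1)
  expect_equal(compute_ld(g, 1, 4), compute_ld(g, 4, 1))
  g0 <- toy_genotypes(cbind(c(0, 0, 0), c(-1, 0, 1)))
  expect_error(compute_ld(g0, 1, 2), "zero-variance")
})

test_that("independent columns at n = 10000 have |r| < 0.05", {
  g <- random_genotypes(10000, 2, seed = 6)
  expect_lt(abs(compute_ld(g, 1, 2)), 0.05)
})

test_that("pca_covariates centers, orthogonalizes and bounds k", {
  g <- random_genotypes(60, 30, seed = 7)
  s <- pca_covariates(g, 4)
  expect_equal(dim(s), c(60L, 4L))
  expect_true(all(abs(colMeans(s)) < 1e-8))
  ortho <- crossprod(s)
  expect_true(all(abs(ortho[upper.tri(ortho)]) < 1e-8))
  expect_equal(ncol(pca_covariates(g, 0)), 0L)
  expect_error(pca_covariates(g, 31), "rank")
})

test_that("the leading component separates two divergent haplotype pools", {
  set.seed(8)
  a <- matrix(rbinom(40 * 60, 2, 0.15) - 1L, 40, 60)
  b <- matrix(rbinom(40 * 60, 2, 0.85) - 1L, 40, 60)
  g <- toy_genotypes(rbind(a, b))
  s <- pca_covariates(g, 1)
  pops <- rep(c(1, 2), each = 40)
  expect_true(max(s[pops == 1, 1]) < min(s[pops == 2, 1]) ||
                min(s[pops == 1, 1]) > max(s[pops == 2, 1]))
})
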