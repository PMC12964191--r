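test_that("percentile threshold leaves the documented counts above", {
  withr::with_seed(1, {
    # distinct by construction (runif alone collides on the 2^32 grid)
    v <- sample(seq_len(290522)) + runif(290522, -0.4, 0.4)
    expect_equal(sum(v > percentile_threshold(v, 99.99)), 29L)
    expect_equal(sum(v > percentile_threshold(v, 99.95)), 145L)
    v100 <- runif(100)
    expect_equal(sum(v100 > percentile_threshold(v100, 99)), 1L)
  })
  expect_error(percentile_threshold(1:10, 0), "percentile")
  expect_error(percentile_threshold(1:10, 100), "percentile")
})

test_that("aggregation matches a brute-force evaluation of the definitions", {
  A <- rbind(c(0.50, 0.20, 0.10, 0.15, 0.05),
             c(0.45, 0.25, 0.05, 0.20, 0.05),
             c(0.05, 0.30, 0.40, 0.15, 0.10))
  Am <- structure(list(A = A, model_seeds = 1:3, method = "IG"),
                  class = "mas_matrix")
  q <- 60
  rep <- aggregate_mas(Am, q)
  # independent brute force straight from the formulas
  m <- nrow(A); L <- ncol(A)
  mu <- sapply(seq_len(L), function(j) mean(A[, j]))
  k <- floor(L * (1 - q / 100))
  theta <- sort(mu, decreasing = TRUE)[k + 1]
  w <- sapply(seq_len(L), function(j) sum(A[, j] > theta) / m)
  amas <- ifelse(mu > theta, w * mu, NA)
  expect_equal(rep$mu, mu)
  expect_equal(rep$theta, theta)
  expect_equal(rep$weights, w)
  expect_equal(rep$amas, amas)
  expect_equal(rep$pal_amas, which(!is.na(amas) & amas > theta))
  expect_equal(rep$pal_common,
               which(sapply(seq_len(L), function(j) all(A[, j] > theta))))
})

test_that("weights are exceedance fractions on the 1/m grid", {
  withr::with_seed(2, {
    for (i in 1:50) {
      m <- sample(1:6, 1)
      L <- 40
      A <- matrix(rexp(m * L), m, L)
      A <- A / rowSums(A)
      Am <- structure(list(A = A, model_seeds = seq_len(m), method = "IG"),
                      class = "mas_matrix")
      rep <- aggregate_mas(Am, 90)
      expect_true(all(rep$weights %in% ((0:m) / m)))
      expect_true(all(rep$amas <= rep$mu, na.rm = TRUE))
    }
  })
})

test_that("PAL_Common is a subset of PAL_AMAS on random MAS matrices", {
  withr::with_seed(3, {
    for (i in 1:1000) {
      m <- sample(1:5, 1)
      L <- sample(c(30, 60), 1)
      A <- matrix(rexp(m * L)^2, m, L)
      A <- A / rowSums(A)
      Am <- structure(list(A = A, model_seeds = seq_len(m), method = "IG"),
                      class = "mas_matrix")
      rep <- aggregate_mas(Am, sample(c(80, 90, 95), 1))
      expect_true(all(rep$pal_common %in% rep$pal_amas))
    }
  })
})

test_that("aggregate is equivariant under position permutations", {
  withr::with_seed(9, {
    A <- matrix(rexp(3 * 30), 3, 30)
    A <- A / rowSums(A)
    perm <- sample(30)
    Am <- structure(list(A = A, model_seeds = 1:3, method = "IG"),
                    class = "mas_matrix")
    Ap <- structure(list(A = A[, perm], model_seeds = 1:3, method = "IG"),
                    class = "mas_matrix")
    r1 <- aggregate_mas(Am, 90)
    r2 <- aggregate_mas(Ap, 90)
    expect_equal(r2$mu, r1$mu[perm])
    expect_equal(r2$weights, r1$weights[perm])
    expect_equal(r2$theta, r1$theta)
    expect_setequal(perm[r2$pal_amas], r1$pal_amas)
  })
})

test_that("aggregate is row-order invariant and m = 1 collapses the sets", {
  withr::with_seed(4, {
    A <- matrix(rexp(4 * 50), 4, 50)
    A <- A / rowSums(A)
    Am <- structure(list(A = A, model_seeds = 1:4, method = "IG"),
                    class = "mas_matrix")
    Am_shuf <- Am
    Am_shuf$A <- A[c(3, 1, 4, 2), ]
    r1 <- aggregate_mas(Am, 90)
    r2 <- aggregate_mas(Am_shuf, 90)
    expect_equal(r1$mu, r2$mu)
    expect_equal(r1$weights, r2$weights)
    expect_equal(r1$pal_amas, r2$pal_amas)
    A1 <- structure(list(A = A[1, , drop = FALSE], model_seeds = 1L,
                         method = "IG"), class = "mas_matrix")
    r <- aggregate_mas(A1, 90)
    expect_equal(r$pal_amas, which(r$mu > r$theta))
    expect_equal(r$pal_common, r$pal_amas)
  })
})

# correlated triple: r(1,2) and r(2,3) strong, r(1,3) weak
correlated_genotypes <- function(seed = 3, n = 400) {
  withr::with_seed(seed, {
    flip <- function(x, p) ifelse(runif(length(x)) < p,
                                  sample(c(-1L, 0L, 1L), length(x), TRUE), x)
    c1 <- sample(c(-1L, 0L, 1L), n, TRUE)
    c2 <- flip(c1, 0.4)
    c3 <- flip(c2, 0.4)
    c4 <- sample(c(-1L, 0L, 1L), n, TRUE)
    toy_genotypes(cbind(c1, c2, c3, c4))
  })
}

test_that("cross-model clumping uses transitive closure over LD edges", {
  g <- correlated_genotypes()
  r12 <- abs(compute_ld(g, 1, 2)); r23 <- abs(compute_ld(g, 2, 3))
  r13 <- abs(compute_ld(g, 1, 3))
  expect_true(r12 > 0.5 && r23 > 0.5 && r13 < 0.5)  # fixture premise
  groups <- clump_cross_model(list(c(1L, 3L), 2L), g, r_threshold = 0.5,
                              amas = c(0.1, 0.5, 0.2, 0.9))
  expect_length(groups, 1L)
  expect_setequal(groups[[1]]$positions, 1:3)
  expect_equal(groups[[1]]$representative, 2L)
  # below threshold: no merging
  groups2 <- clump_cross_model(list(1L, 4L), g, r_threshold = 0.5)
  expect_length(groups2, 2L)
  expect_length(clump_cross_model(list(), g), 0L)
})

test_that("distance blocks split on gaps and chromosomes", {
  g <- genotype_matrix(
    matrix(rep(c(-1L, 0L, 1L), 4), 3, 4),
    data.frame(chrom = c("1", "1", "1", "2"),
               bp = c(1000000L, 1050000L, 1150001L, 1000000L),
               id = paste0("v", 1:4)),
    c("s1", "s2", "s3"))
  b <- block_clump_distance(1:2, g)
  expect_length(b, 1L)
  b2 <- block_clump_distance(c(2L, 3L), g)
  expect_length(b2, 2L)
  b3 <- block_clump_distance(c(3L, 4L), g)
  expect_length(b3, 2L)
  expect_length(block_clump_distance(integer(), g), 0L)
})

test_that("PAL reports render and persist", {
  withr::with_seed(6, {
    g <- random_genotypes(100, 40, seed = 7)
    A <- matrix(rexp(3 * 40), 3, 40)
    A <- A / rowSums(A)
    Am <- structure(list(A = A, model_seeds = 1:3, method = "IG"),
                    class = "mas_matrix")
    rep <- finalize_pal(aggregate_mas(Am, 90), g)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_pal_report(rep, g, path)
    tab <- read.delim(path)
    expect_true(all(c("mu", "w", "amas", "in_pal_amas") %in% names(tab)))
    expect_true(file.exists(paste0(path, ".json")))
  })
})
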