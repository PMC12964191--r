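test_that("per-SNP logistic regression matches glm on a small fixture", {
  withr::with_seed(1, {
    g <- random_genotypes(200, 5, seed = 2)
    covs <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, paste0("PC", 1:3)))
    eta <- 0.8 * g$values[, 2] + 0.5 * covs[, 1]
    y <- rbinom(200, 1, plogis(eta))
    res <- logistic_gwas(g, y, covariates = covs)
    for (j in 1:5) {
      ref <- glm(y ~ g$values[, j] + covs, family = binomial(),
                 control = glm.control(epsilon = 1e-12))
      expect_equal(res$table$beta[j], unname(coef(ref)[2]), tolerance = 1e-6)
      expect_equal(res$table$se[j],
                   unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-6)
      expect_equal(res$table$p[j],
                   unname(summary(ref)$coefficients[2, 4]), tolerance = 1e-6)
    }
    expect_equal(res$bonferroni_threshold, 0.05 / 5)
  })
})

test_that("the genome-wide Bonferroni threshold rounds to 1.7e-7", {
  expect_equal(signif(0.05 / 290522, 2), 1.7e-7)
})

test_that("Wald P-values are calibrated on null SNPs", {
  withr::with_seed(3, {
    g <- random_genotypes(2000, 200, seed = 4)
    y <- rbinom(2000, 1, 0.2)
    res <- logistic_gwas(g, y)
    p <- res$table$p[!is.na(res$table$p)]
    hits <- sum(p < 0.05)
    # binomial(200, 0.05): mean 10, sd 3.08
    expect_gte(hits, 2)
    expect_lte(hits, 20)
  })
})

test_that("degenerate and separated SNPs are flagged, not zeroed", {
  vals <- cbind(rep(0L, 40),
                c(rep(-1L, 20), rep(1L, 20)),
                sample(c(-1L, 0L, 1L), 40, TRUE))
  g <- toy_genotypes(vals)
  y <- c(rep(0L, 20), rep(1L, 20))  # perfectly separated by SNP 2
  res <- suppressMessages(logistic_gwas(g, y))
  expect_equal(res$table$flag[1], "zero-variance")
  expect_true(res$table$flag[2] %in% c("separation", "non-convergence"))
  expect_true(is.na(res$table$p[1]) && is.na(res$table$p[2]))
  # the denominator still counts all attempted tests
  expect_equal(res$bonferroni_threshold, 0.05 / 3)
})

eval_fixture <- function() {
  # 6 causal positions on two chromosomes, known classes
  g <- genotype_matrix(
    matrix(rep_len(c(-1L, 0L, 1L), 3 * 40), 3, 40),
    data.frame(chrom = rep(c("1", "2"), each = 20),
               bp = rep(seq(1e6, by = 50000L, length.out = 20), 2),
               id = paste0("v", 1:40)),
    c("s1", "s2", "s3"))
  e <- structure(
    list(dominant = c(1L, 22L), recessive = 5L,
         pairs = matrix(c(10L, 30L), ncol = 2),
         triplets = matrix(c(15L, 35L, 40L), ncol = 3),
         beta_single = setNames(rep(1, 3), c("1", "22", "5")),
         beta_pair = 1, beta_triplet = 1, n_causal = 8L, seed = 0L),
    class = "effect_spec")
  list(g = g, e = e)
}

test_that("blocks are labelled TP within +/-100 kb and FP outside", {
  fx <- eval_fixture()
  # detected SNP 50 kb from causal bp -> TP
  blocks <- block_clump_distance(2L, fx$g)  # bp 1,050,000; causal v1 at 1e6
  ev <- label_detections(blocks, causal_table(fx$e, fx$g))
  expect_equal(ev$tp, 1L)
  expect_equal(ev$fp, 0L)
  # boundary: 1,100,001 vs causal 1,000,000 is outside the closed window
  g2 <- genotype_matrix(
    matrix(c(-1L, 0L, 1L, -1L, 0L, 1L), 3, 2),
    data.frame(chrom = "1", bp = c(1000000L, 2100001L), id = c("a", "b")),
    c("s1", "s2", "s3"))
  causal <- data.frame(position = 1L, chrom = "1", bp = 2000000L,
                       class = "dominant")
  ev2 <- label_detections(block_clump_distance(2L, g2), causal)
  expect_equal(ev2$fp, 1L)
  expect_equal(ev2$tp, 0L)
})

test_that("nearby detections collapse to one block and count one TP", {
  fx <- eval_fixture()
  blocks <- block_clump_distance(c(1L, 2L, 3L), fx$g)  # 50 kb apart
  expect_length(blocks, 1L)
  ev <- label_detections(blocks, causal_table(fx$e, fx$g))
  expect_equal(ev$tp + ev$fp, length(blocks))
  expect_equal(ev$tp, 1L)
})

test_that("label_detections is invariant to block order", {
  fx <- eval_fixture()
  blocks <- block_clump_distance(c(2L, 25L, 39L), fx$g)
  ev_a <- label_detections(blocks, causal_table(fx$e, fx$g))
  ev_b <- label_detections(rev(blocks), causal_table(fx$e, fx$g))
  expect_equal(ev_a$tp, ev_b$tp)
  expect_equal(ev_a$fp, ev_b$fp)
})

test_that("precision and recall agree with a brute-force double loop", {
  fx <- eval_fixture()
  detected <- c(2L, 11L, 24L, 37L)
  out <- evaluate_detections(detected, fx$e, fx$g)
  expect_equal(out$metrics$tp + out$metrics$fp, length(out$eval$blocks))
  # brute force recall: causal positions within 100 kb of any detected SNP
  ct <- causal_table(fx$e, fx$g)
  det_bp <- fx$g$variants[detected, ]
  hit <- sapply(seq_len(nrow(ct)), function(i) {
    any(det_bp$chrom == ct$chrom[i] & abs(det_bp$bp - ct$bp[i]) <= 1e5)
  })
  expect_equal(out$metrics$recall, sum(hit) / fx$e$n_causal)
  expect_true(out$metrics$precision >= 0 && out$metrics$precision <= 1)
  # no detections: precision absent, recall zero
  empty <- evaluate_detections(integer(), fx$e, fx$g)
  expect_true(is.na(empty$metrics$precision))
  expect_equal(empty$metrics$recall, 0)
})

test_that("effect-type breakdown attributes detected causal positions", {
  fx <- eval_fixture()
  out <- evaluate_detections(c(10L, 30L), fx$e, fx$g)  # both pair members
  bd <- out$breakdown
  expect_equal(unname(bd$per_class["two-way"]), 2)
  expect_equal(unname(bd$split["interactive"]), 2)
  expect_equal(unname(bd$split["dominant_recessive"]), 0)
  expect_equal(sum(bd$per_class), sum(out$eval$causal_detected))
})

test_that("zero-noise strong-signal smoke: both routes detect a causal block", {
  # end-to-end sanity: with k = 0 and 20 causal SNPs among 1000, both the
  # logistic baseline at Bonferroni and the IG-PAL route (percentile
  # chosen to leave ~10 candidates at this L; the genome-wide strict
  # percentile leaves zero candidates below L = 10^4) find real signal
  g <- generate_genotypes(1200, 1000, block_size = 10, seed = 21)
  e <- assign_effects(g, 20, seed = 22)
  ps <- simulate_phenotypes(g, e, k = 0, seed = 23)
  cfg <- mlp_config(input_size = 1000, epochs = 150, learning_rate = 3e-4,
                    n_val_cases = 30L, n_val_controls = 30L, seed = 1)
  models <- train_ensemble(g, ps$y_binary, cfg, seeds = c(31, 32, 33))
  mas <- ensemble_mas(models, g, ps$y_binary, method = "ig", n_steps = 20)
  rep <- aggregate_mas(mas_matrix(mas), 99)
  expect_gte(length(rep$pal_amas), 1)
  pal_eval <- evaluate_detections(rep$pal_amas, e, g)
  expect_gte(pal_eval$metrics$tp, 1)

  lr <- logistic_gwas(g, ps$y_binary)
  hits <- which(!is.na(lr$table$p) & lr$table$p < lr$bonferroni_threshold)
  expect_gte(length(hits), 1)
  lr_eval <- evaluate_detections(hits, e, g)
  expect_gte(lr_eval$metrics$tp, 1)
})

test_that("external association results import against the variant frame", {
  g <- random_genotypes(10, 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tp", paste(g$variants$id, c(0.1, 0.2, 0.3, 0.4),
                                      sep = "\t")), path)
  res <- import_association(path, g)
  expect_equal(res$table$p, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(res$n_tested, 4L)
})
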