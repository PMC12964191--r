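test_that("parameter counts match the closed form and printed architectures", {
  cfg <- mlp_config(input_size = 500, hidden = c(7, 3), seed = 1)
  m <- build_model(cfg)
  expect_equal(n_parameters(m), count_mlp_parameters(500, 7, 3))
  expect_equal(n_parameters(m), 500 * 7 + 7 + 7 * 3 + 3 + 3 + 1)
  # the small (single-chromosome) preset: 20714 -> 82 -> 8 -> 1
  expect_equal(count_mlp_parameters(20714, 82, 8), 1699303)
})

test_that("default hidden sizing rule applies floors and scaling", {
  expect_equal(default_hidden_sizes(5000), c(8L, 4L))
  expect_equal(default_hidden_sizes(290522), c(291L, 29L))
  expect_equal(default_hidden_sizes(100), c(8L, 4L))
})

test_that("untrained model outputs lie strictly inside (0, 1)", {
  m <- build_model(mlp_config(input_size = 50, seed = 2))
  x <- matrix(sample(c(-1, 0, 1), 500, replace = TRUE), 10, 50)
  p <- predict(m, x)
  expect_true(all(p > 0 & p < 1))
})

test_that("initialisation is seed-reproducible and seed-sensitive", {
  cfg <- mlp_config(input_size = 40, seed = 3)
  expect_identical(build_model(cfg)$W1, build_model(cfg)$W1)
  cfg2 <- cfg; cfg2$seed <- 4L
  expect_false(identical(build_model(cfg)$W1, build_model(cfg2)$W1))
})

test_that("balance_dataset duplicates cases and halves controls", {
  ids <- balance_dataset(seq_len(1814), 10000 + seq_len(7325), seed = 1)
  expect_equal(sum(ids <= 1814), 2 * 1814)
  expect_equal(sum(ids > 10000), floor(7325 / 2))
  expect_equal(as.vector(table(ids[ids <= 1814])), rep(2L, 1814))
  ids2 <- balance_dataset(1:10, 11:30, seed = 2)
  expect_equal(sum(ids2 <= 10), 20L)
  expect_equal(sum(ids2 > 10), 10L)
  expect_error(balance_dataset(integer(), 1:3), "nonempty")
})

test_that("training is bitwise deterministic and records full histories", {
  fix <- trained_fixture()
  m2 <- suppressWarnings(train(build_model(fix$cfg), fix$g,
                               fix$ps$y_binary, fix$cfg))
  expect_identical(fix$model$history, m2$history)
  expect_identical(fix$model$W1, m2$W1)
  expect_length(fix$model$history$train, fix$cfg$epochs)
  expect_length(fix$model$history$validation, fix$cfg$epochs)
})

test_that("a separable SNP is learned without noise injection", {
  set.seed(5)
  n <- 240
  vals <- matrix(sample(c(-1L, 0L, 1L), n * 20, replace = TRUE), n, 20)
  g <- toy_genotypes(vals)
  labels <- as.integer(vals[, 7] == 1L)
  labels[1:2] <- c(0L, 1L)  # ensure both classes even in tiny splits
  cfg <- mlp_config(input_size = 20, epochs = 80, input_mask_p = 0,
                    hidden_dropout_p = 0, input_noise_sd = 0,
                    label_noise_sd = 0, learning_rate = 1e-2,
                    n_val_cases = 8L, n_val_controls = 8L,
                    batch_size = 64L, seed = 6)
  m <- train(build_model(cfg), g, labels, cfg)
  expect_lt(m$history$validation[cfg$epochs], m$history$validation[1])
  expect_lt(m$history$validation[cfg$epochs], 0.3)
})

test_that("training validates labels and split sizes", {
  fix <- trained_fixture()
  expect_error(train(fix$model, fix$g, rep(2L, nrow(fix$g$values)), fix$cfg),
               "binary")
  cfg <- fix$cfg
  cfg$n_val_cases <- 10000L
  expect_error(train(build_model(cfg), fix$g, fix$ps$y_binary, cfg),
               "validation split")
})

test_that("persisted models reload with identical outputs", {
  fix <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fix$model, path)
  m2 <- load_model(path)
  probe <- fix$g$values[1:20, ]
  expect_identical(predict(fix$model, probe), predict(m2, probe))
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("ensembles differ by seed; permuted-label models learn less", {
  set.seed(7)
  n <- 300
  vals <- matrix(sample(c(-1L, 0L, 1L), n * 30, replace = TRUE), n, 30)
  g <- toy_genotypes(vals)
  labels <- as.integer(vals[, 3] == 1L)
  labels[1:2] <- c(0L, 1L)
  cfg <- mlp_config(input_size = 30, epochs = 60, input_mask_p = 0,
                    hidden_dropout_p = 0, input_noise_sd = 0,
                    label_noise_sd = 0, learning_rate = 1e-2,
                    n_val_cases = 10L, n_val_controls = 10L,
                    batch_size = 64L, seed = 1)
  ens <- train_ensemble(g, labels, cfg, seeds = c(11, 12))
  expect_length(ens, 2L)
  expect_false(identical(ens[[1]]$W1, ens[[2]]$W1))
  expect_warning(train_ensemble(g, labels, cfg, seeds = c(11, 11)),
                 "duplicate")
  nulls <- train_ensemble(g, labels, cfg, seeds = c(11, 12),
                          permute_labels = TRUE, permutation_seed = 5)
  expect_equal(nulls[[1]]$label_permutation_seed, 5L)
  expect_equal(nulls[[2]]$label_permutation_seed, 6L)
  # the informative SNP no longer predicts permuted labels
  true_final <- min(sapply(ens, function(m) tail(m$history$validation, 1)))
  null_final <- min(sapply(nulls, function(m) tail(m$history$validation, 1)))
  expect_lt(true_final, null_final)
})

test_that("noise-free training follows the frozen reference trajectory", {
  # plain deterministic MLP fit: no masking, no dropout, no noise
  g <- random_genotypes(80, 12, seed = 9)
  labels <- as.integer(g$values[, 4] >= 0)
  labels[1:2] <- c(0L, 1L)
  cfg <- mlp_config(input_size = 12, hidden = c(5, 3), epochs = 25,
                    input_mask_p = 0, hidden_dropout_p = 0,
                    input_noise_sd = 0, label_noise_sd = 0,
                    learning_rate = 1e-2, n_val_cases = 5L,
                    n_val_controls = 5L, batch_size = 32L, seed = 10)
  m <- train(build_model(cfg), g, labels, cfg)
  expect_equal(tail(m$history$train, 1), 0.029303955617, tolerance = 1e-6)
  expect_equal(tail(m$history$validation, 1), 0.093383694238, tolerance = 1e-6)
})
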