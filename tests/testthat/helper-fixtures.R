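# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary fixtures are stored.

# Small genotype matrix with explicit values (rows = individuals).
toy_genotypes <- function(values, bp = NULL, chrom = "1") {
  values <- as.matrix(values)
  if (is.null(bp)) bp <- seq_len(ncol(values)) * 1000L
  genotype_matrix(
    values,
    data.frame(chrom = chrom, bp = bp,
               id = sprintf("snp%d", seq_len(ncol(values)))),
    sprintf("s%d", seq_len(nrow(values)))
  )
}

# Random ternary matrix with independent columns.
random_genotypes <- function(n, L, seed = 1, maf = 0.3) {
  withr::with_seed(seed, {
    vals <- matrix(stats::rbinom(n * L, 2L, maf) - 1L, n, L)
    # guard against zero-variance columns
    vals[1, ] <- -1L
    vals[2, ] <- 1L
    toy_genotypes(vals)
  })
}

# A model that computes exactly f(x) = w . x (identity output) or
# sigmoid(w . x): hidden layers collapsed to identity pass-throughs.
linear_model <- function(w, output = "identity") {
  cfg <- mlp_config(input_size = length(w), hidden = c(1L, 1L),
                    input_mask_p = 0, hidden_dropout_p = 0,
                    activations = c("identity", "identity"),
                    output = output, seed = 1L)
  m <- build_model(cfg)
  m$W1 <- matrix(w, ncol = 1L)
  m$b1 <- 0
  m$W2 <- matrix(1, 1L, 1L)
  m$b2 <- 0
  m$W3 <- matrix(1, 1L, 1L)
  m$b3 <- 0
  m
}

# A small trained nonlinear model plus its data, memoised across tests.
trained_fixture_env <- new.env()
trained_fixture <- function() {
  if (is.null(trained_fixture_env$fix)) {
    g <- generate_genotypes(300, 120, block_size = 6L, seed = 42)
    e <- assign_effects(g, 20, seed = 7)
    ps <- simulate_phenotypes(g, e, k = 0.5, seed = 9)
    cfg <- mlp_config(input_size = 120, epochs = 40,
                      n_val_cases = 10L, n_val_controls = 10L,
                      batch_size = 64L, seed = 3L)
    model <- suppressWarnings(train(build_model(cfg), g, ps$y_binary, cfg))
    trained_fixture_env$fix <- list(g = g, e = e, ps = ps, cfg = cfg,
                                    model = model)
  }
  trained_fixture_env$fix
}
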