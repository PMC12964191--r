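#' Model configuration for the genotype classifier
#'
#' The classifier is a fully connected feedforward network:
#' input-masking dropout -> affine(L -> h1) -> dropout -> ReLU ->
#' affine(h1 -> h2) -> dropout -> GELU -> affine(h2 -> 1) -> sigmoid.
#' The input-masking layer randomly zeroes a large proportion of SNP
#' inputs at every batch (inverted-dropout semantics: retained inputs are
#' scaled by 1/(1-p)), which acts as aggressive regularisation against
#' the huge feature-to-sample ratio of genome-wide data.
#'
#' Defaults for arbitrary input size follow the rule
#' `h1 = max(8, round(L/1000))`, `h2 = max(4, round(h1/10))`.
#'
#' @param input_size Number of SNP inputs (L).
#' @param hidden Length-2 integer vector (h1, h2); `NULL` applies the
#'   default sizing rule.
#' @param input_mask_p Input-masking dropout probability in `[0, 1)`.
#' @param hidden_dropout_p Hidden dropout probability in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param weight_decay Adam weight decay (L2).
#' @param epochs Training epochs (fixed; final-epoch weights are kept).
#' @param batch_size Minibatch size.
#' @param label_noise_sd SD of Gaussian noise added to 0/1 labels each
#'   batch (clipped back to `[0, 1]`).
#' @param input_noise_sd SD of Gaussian noise added to genotype inputs
#'   each batch.
#' @param n_val_cases,n_val_controls Validation split sizes drawn from
#'   the original cases/controls before balancing.
#' @param seed Integer seed controlling initialisation and training
#'   randomness.
#' @param activations Hidden activations, length 2, each of `"relu"`,
#'   `"gelu"`, `"identity"`.
#' @param output Output activation, `"sigmoid"` or `"identity"`.
#' @return A validated list of class `mlp_config`.
#' @export
mlp_config <- function(input_size,
                       hidden = NULL,
                       input_mask_p = 0.5,
                       hidden_dropout_p = 0.6,
                       learning_rate = 1e-4,
                       weight_decay = 1e-3,
                       epochs = 200L,
                       batch_size = 256L,
                       label_noise_sd = 0.1,
                       input_noise_sd = 0.1,
                       n_val_cases = 50L,
                       n_val_controls = 50L,
                       seed = 1L,
                       activations = c("relu", "gelu"),
                       output = "sigmoid") {
  if (is.null(hidden)) hidden <- default_hidden_sizes(input_size)
  cfg <- list(input_size = as.integer(input_size),
              hidden1 = as.integer(hidden[1]), hidden2 = as.integer(hidden[2]),
              input_mask_p = input_mask_p,
              hidden_dropout_p = hidden_dropout_p,
              learning_rate = learning_rate, weight_decay = weight_decay,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              label_noise_sd = label_noise_sd, input_noise_sd = input_noise_sd,
              n_val_cases = as.integer(n_val_cases),
              n_val_controls = as.integer(n_val_controls),
              seed = as.integer(seed),
              activations = match.arg(activations,
                                      c("relu", "gelu", "identity"),
                                      several.ok = TRUE),
              output = match.arg(output, c("sigmoid", "identity")))
  validate_mlp_config(cfg)
  structure(cfg, class = "mlp_config")
}

validate_mlp_config <- function(cfg) {
  stopifnot(cfg$input_size >= 1L, cfg$hidden1 >= 1L, cfg$hidden2 >= 1L,
            cfg$epochs >= 1L, cfg$batch_size >= 1L,
            cfg$learning_rate > 0, cfg$weight_decay >= 0,
            cfg$label_noise_sd >= 0, cfg$input_noise_sd >= 0,
            length(cfg$activations) == 2L)
  for (p in c(cfg$input_mask_p, cfg$hidden_dropout_p)) {
    if (p < 0 || p >= 1) stop("dropout probabilities must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Default hidden-layer sizing rule
#' @param L Input size.
#' @return Integer vector (h1, h2).
#' @export
default_hidden_sizes <- function(L) {
  h1 <- max(8L, as.integer(round(L / 1000)))
  h2 <- max(4L, as.integer(round(h1 / 10)))
  c(h1, h2)
}

#' Named architecture presets
#'
#' `"genome-wide"`: 290522 -> 290 -> 29 -> 1 with input mask p = 0.99,
#' 1000 epochs, learning rate 1e-5, validation 150 + 150.
#' `"small"`: 20714 -> 82 -> 8 -> 1 with input mask p = 0.50, 100
#' epochs, validation 100 + 100 (single-chromosome scale).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [mlp_config()].
#' @return An `mlp_config`.
#' @export
mlp_preset <- function(name = c("genome-wide", "small"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "genome-wide" = list(input_size = 290522L, hidden = c(290L, 29L),
                         input_mask_p = 0.99, hidden_dropout_p = 0.6,
                         learning_rate = 1e-5, weight_decay = 1e-3,
                         epochs = 1000L, batch_size = 256L,
                         n_val_cases = 150L, n_val_controls = 150L),
    "small" = list(input_size = 20714L, hidden = c(82L, 8L),
                   input_mask_p = 0.5, hidden_dropout_p = 0.6,
                   learning_rate = 1e-5, weight_decay = 1e-3,
                   epochs = 100L, batch_size = 256L,
                   n_val_cases = 100L, n_val_controls = 100L)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(mlp_config, base)
}

#' Build an (untrained) classifier
#'
#' Weights are initialised with the Kaiming-uniform scheme
#' (`U(-sqrt(6/fan_in), sqrt(6/fan_in))` for weights,
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` for biases) from `config$seed`.
#'
#' @param config An [mlp_config()].
#' @return An object of class `palnn_model` with weight matrices
#'   `W1 (L x h1)`, `W2 (h1 x h2)`, `W3 (h2 x 1)` and biases.
#' @export
build_model <- function(config) {
  validate_mlp_config(config)
  L <- config$input_size; h1 <- config$hidden1; h2 <- config$hidden2
  kaiming <- function(fan_in, fan_out) {
    b <- sqrt(6 / fan_in)
    matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
  }
  bias_init <- function(fan_in, n) {
    b <- 1 / sqrt(fan_in)
    stats::runif(n, -b, b)
  }
  with_seed(config$seed, {
    structure(
      list(W1 = kaiming(L, h1), b1 = bias_init(L, h1),
           W2 = kaiming(h1, h2), b2 = bias_init(h1, h2),
           W3 = kaiming(h2, 1L), b3 = bias_init(h2, 1L),
           config = config, history = NULL,
           label_permutation_seed = NULL),
      class = "palnn_model"
    )
  })
}

#' Number of trainable parameters
#'
#' Counts weights and biases by introspection over the stored tensors;
#' equals the closed form `L*h1 + h1 + h1*h2 + h2 + h2 + 1`.
#'
#' @param model A `palnn_model`.
#' @return Integer-valued count (numeric to avoid 32-bit overflow).
#' @export
n_parameters <- function(model) {
  sum(vapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
             function(x) as.numeric(length(x)), numeric(1)))
}

#' Closed-form parameter count of the architecture
#' @param L,h1,h2 Layer sizes.
#' @return Numeric parameter count.
#' @export
count_mlp_parameters <- function(L, h1, h2) {
  L * h1 + h1 + h1 * h2 + h2 + h2 + 1
}

act_fun <- function(name) {
  switch(name,
         relu = function(x) pmax(x, 0),
         gelu = function(x) x * stats::pnorm(x),
         identity = function(x) x)
}

act_grad <- function(name) {
  switch(name,
         relu = function(x) (x > 0) + 0,
         gelu = function(x) stats::pnorm(x) + x * stats::dnorm(x),
         identity = function(x) array(1, dim(x) %||% length(x)))
}

# Forward pass without dropout (deterministic; used for prediction and
# attribution). X: n x L matrix. Returns list with pre-activations.
mlp_forward <- function(model, X, keep = FALSE) {
  cfg <- model$config
  Z1 <- sweep(X %*% model$W1, 2L, model$b1, "+")
  A1 <- act_fun(cfg$activations[1])(Z1)
  Z2 <- sweep(A1 %*% model$W2, 2L, model$b2, "+")
  A2 <- act_fun(cfg$activations[2])(Z2)
  z3 <- drop(A2 %*% model$W3) + model$b3
  out <- if (cfg$output == "sigmoid") stats::plogis(z3) else z3
  if (keep) list(out = out, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, z3 = z3)
  else out
}

#' Predict case probabilities
#'
#' Dropout layers are inactive at prediction time.
#'
#' @param object A `palnn_model`.
#' @param newdata Numeric matrix (n x L) of ternary genotypes, or a
#'   [genotype_matrix].
#' @param ... Unused.
#' @return Numeric vector of outputs (probabilities under the sigmoid
#'   output).
#' @export
predict.palnn_model <- function(object, newdata, ...) {
  X <- as_input_matrix(object, newdata)
  mlp_forward(object, X)
}

as_input_matrix <- function(model, x) {
  if (inherits(x, "genotype_matrix")) x <- x$values
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != model$config$input_size) {
    stop("input has ", ncol(x), " features; model expects ",
         model$config$input_size)
  }
  x
}

# Gradient of the scalar output w.r.t. every input coordinate, for a
# batch: returns n x L matrix.
mlp_input_gradient <- function(model, X) {
  cfg <- model$config
  f <- mlp_forward(model, X, keep = TRUE)
  dout <- if (cfg$output == "sigmoid") f$out * (1 - f$out) else rep(1, nrow(X))
  dA2 <- dout %o% drop(model$W3)
  dZ2 <- dA2 * act_grad(cfg$activations[2])(f$Z2)
  dA1 <- dZ2 %*% t(model$W2)
  dZ1 <- dA1 * act_grad(cfg$activations[1])(f$Z1)
  dZ1 %*% t(model$W1)
}

#' @export
print.palnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("palnn_model: %d -> %d -> %d -> 1 (%s/%s/%s)\n",
              cfg$input_size, cfg$hidden1, cfg$hidden2,
              cfg$activations[1], cfg$activations[2], cfg$output))
  cat(sprintf("  %s parameters; input mask p = %.2f\n",
              format(n_parameters(x), big.mark = ","), cfg$input_mask_p))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; final train/val loss %.4f / %.4f\n",
                length(x$history$train), utils::tail(x$history$train, 1),
                utils::tail(x$history$validation, 1)))
  }
  invisible(x)
}

#' Persist a trained model
#'
#' Writes the model in R's native serialised form plus a JSON metadata
#' sidecar (configuration, seeds, final losses).
#'
#' @param model A `palnn_model`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(config = unclass(model$config),
               label_permutation_seed = model$label_permutation_seed,
               final_train_loss = utils::tail(model$history$train, 1),
               final_validation_loss = utils::tail(model$history$validation, 1))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Reload a persisted model
#' @param path Path written by [save_model()].
#' @return A `palnn_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "palnn_model"))
  m
}
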