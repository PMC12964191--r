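#' Balance cases and controls for training
#'
#' Every case appears exactly twice (duplication) and controls are
#' reduced to a uniformly subsampled half (floor(n/2), without
#' replacement), which brings typical case:control ratios near 1:1
#' without reweighting the loss.
#'
#' @param case_ids Vector of case identifiers (indices or names).
#' @param control_ids Vector of control identifiers.
#' @param seed Integer seed for the control subsample.
#' @return Vector of training identifiers (cases duplicated, controls
#'   subsampled), shuffled.
#' @export
balance_dataset <- function(case_ids, control_ids, seed = 1L) {
  if (length(case_ids) == 0L || length(control_ids) == 0L) {
    stop("case and control id lists must be nonempty")
  }
  with_seed(seed, {
    controls <- sample(control_ids, floor(length(control_ids) / 2))
    sample(c(rep(case_ids, 2L), controls))
  })
}

#' Train the classifier
#'
#' Training follows a fixed recipe: a validation split of
#' `n_val_cases + n_val_controls` samples is drawn (seeded) from the
#' original cases/controls before balancing; the remaining samples are
#' balanced with [balance_dataset()]; at every minibatch, fresh Gaussian
#' noise `N(0, input_noise_sd^2)` is added to genotype inputs and
#' `N(0, label_noise_sd^2)` to the 0/1 labels (then clipped to `[0, 1]`),
#' the input mask and hidden dropout masks are redrawn, and a binary
#' cross-entropy loss on the sigmoid output is minimised with Adam
#' (learning rate and weight decay from the config). The epoch count is
#' fixed — no early stopping or best-epoch selection — and the
#' final-epoch parameters are returned with the full per-epoch train and
#' validation loss history.
#'
#' The whole loop is deterministic given `config$seed`: reruns yield
#' bitwise-identical histories.
#'
#' @param model An untrained `palnn_model` from [build_model()] (its
#'   config drives training), or `NULL` to build one from `config`.
#' @param g A [genotype_matrix] (or plain numeric matrix).
#' @param labels Integer 0/1 vector aligned with the rows of `g`.
#' @param config Optional [mlp_config()] overriding `model$config`.
#' @return The trained `palnn_model` with `history` filled in
#'   (`$train`, `$validation`, one entry per epoch).
#' @export
train <- function(model = NULL, g, labels, config = NULL) {
  X <- if (inherits(g, "genotype_matrix")) g$values else as.matrix(g)
  storage.mode(X) <- "double"
  if (is.null(config)) config <- model$config
  if (is.null(model)) model <- build_model(config)
  if (length(labels) != nrow(X)) stop("labels must align with genotype rows")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  cfg <- config
  if (cfg$output != "sigmoid") {
    stop("training requires the sigmoid output (binary cross-entropy)")
  }

  cases <- which(labels == 1L)
  controls <- which(labels == 0L)
  if (cfg$n_val_cases >= length(cases) ||
      cfg$n_val_controls >= length(controls)) {
    stop("validation split (", cfg$n_val_cases, " cases + ",
         cfg$n_val_controls, " controls) exceeds available class counts (",
         length(cases), " cases, ", length(controls), " controls)")
  }
  split <- with_seed(derive_seed(cfg$seed, "val-split"), {
    list(val_cases = sample(cases, cfg$n_val_cases),
         val_controls = sample(controls, cfg$n_val_controls))
  })
  val_idx <- c(split$val_cases, split$val_controls)
  train_cases <- setdiff(cases, split$val_cases)
  train_controls <- setdiff(controls, split$val_controls)
  train_idx <- balance_dataset(train_cases, train_controls,
                               seed = derive_seed(cfg$seed, "balance"))

  act_code <- function(a) match(a, c("identity", "relu", "gelu")) - 1L
  res <- cpp_train_mlp(
    model$W1, model$b1, model$W2, model$b2, model$W3, model$b3,
    X[train_idx, , drop = FALSE], as.numeric(labels[train_idx]),
    X[val_idx, , drop = FALSE], as.numeric(labels[val_idx]),
    cfg$input_mask_p, cfg$hidden_dropout_p,
    cfg$input_noise_sd, cfg$label_noise_sd,
    cfg$learning_rate, cfg$weight_decay,
    cfg$epochs, cfg$batch_size,
    act_code(cfg$activations[1]), act_code(cfg$activations[2]),
    derive_seed(cfg$seed, "train-loop")
  )
  model$W1 <- res$W1; model$b1 <- drop(res$b1)
  model$W2 <- res$W2; model$b2 <- drop(res$b2)
  model$W3 <- res$W3; model$b3 <- drop(res$b3)
  model$history <- list(train = drop(res$history_train),
                        validation = drop(res$history_val))
  model$config <- cfg
  model
}

#' Train an ensemble of models across seeds
#'
#' One model is trained per seed (distinct initialisation, distinct
#' training randomness). With `permute_labels = TRUE` the label vector is
#' shuffled before training — by default an independent shuffle per model
#' (seeded by `permutation_seed + model index - 1`); with
#' `shared_permutation = TRUE` a single shuffle (from `permutation_seed`)
#' is shared by all models. Permuted-label ensembles provide the null
#' models for significance estimation.
#'
#' @param g A [genotype_matrix].
#' @param labels Binary labels.
#' @param config An [mlp_config()]; its `seed` field is replaced per
#'   model.
#' @param seeds Integer vector of model seeds (duplicates warn).
#' @param permute_labels Train against shuffled labels.
#' @param permutation_seed Base seed of the label shuffle(s).
#' @param shared_permutation All models share one shuffle.
#' @return List of trained `palnn_model`s.
#' @export
train_ensemble <- function(g, labels, config, seeds,
                           permute_labels = FALSE,
                           permutation_seed = 1L,
                           shared_permutation = FALSE) {
  if (length(seeds) < 1L) stop("at least one seed required")
  if (anyDuplicated(seeds)) warning("duplicate seeds in ensemble")
  shared <- if (permute_labels && shared_permutation) {
    with_seed(permutation_seed, sample(labels))
  }
  lapply(seq_along(seeds), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    y <- labels
    perm_seed <- NULL
    if (permute_labels) {
      if (shared_permutation) {
        y <- shared
        perm_seed <- as.integer(permutation_seed)
      } else {
        perm_seed <- as.integer(permutation_seed + i - 1L)
        y <- with_seed(perm_seed, sample(labels))
      }
    }
    m <- train(build_model(cfg), g, y, cfg)
    m$label_permutation_seed <- perm_seed
    m
  })
}

#' Write per-epoch loss curves as TSV
#' @param model A trained `palnn_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  tab <- data.frame(epoch = seq_along(model$history$train),
                    train_loss = model$history$train,
                    validation_loss = model$history$validation)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
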