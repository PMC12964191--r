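#' Read and validate a run configuration
#'
#' Run configurations are JSON files (see
#' `system.file("extdata", package = "palnn")` for shipped presets
#' covering the six simulation scenarios and a desk-scale smoke setup).
#' Fields: `out_dir`; `genotypes` (generator parameters, or `path` +
#' `format` to load existing data); `scenario` (`k`, `n_causal`,
#' `case_fraction`); `model` (either `preset` or [mlp_config()]
#' overrides); `m`; `m_null`; `method` (`ig`/`sm`/`pm`); `theta_percentile`
#' (or `"strict"`/`"relaxed"`); `n_reps`; `master_seed`.
#'
#' @param config Path to a JSON file, or a list already in memory.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(out_dir = ".", m = 5L, m_null = 3L, method = "ig",
                   theta_percentile = 99.99, n_reps = 100L,
                   r_threshold = 0.5, n_steps = 50L, master_seed = 1L,
                   scenario = list(k = 1, n_causal = 20L,
                                   case_fraction = 1814 / 9139))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.character(config$theta_percentile)) {
    config$theta_percentile <- switch(config$theta_percentile,
                                      strict = 99.99, relaxed = 99.95,
                                      as.numeric(config$theta_percentile))
  }
  if (config$theta_percentile <= 0 || config$theta_percentile >= 100) {
    stop("theta_percentile must lie in (0, 100)")
  }
  config$method <- match.arg(config$method, c("ig", "sm", "pm"))
  structure(config, class = "run_config")
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact '", path,
         "'; run stage '", producer, "' first")
  }
  path
}

model_config_from <- function(config, input_size) {
  mc <- config$model %||% list()
  if (!is.null(mc$preset)) {
    args <- mc[setdiff(names(mc), "preset")]
    do.call(mlp_preset, c(list(name = mc$preset), args))
  } else {
    args <- mc
    args$input_size <- input_size
    do.call(mlp_config, args)
  }
}

write_manifest <- function(config, stage, outputs, seeds = NULL) {
  man <- list(
    stage = stage,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("palnn")),
    master_seed = config$master_seed,
    seeds = seeds,
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  path <- stage_path(config, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man[setdiff(names(man), "time")], path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Orchestrates the end-to-end workflow: genotype simulation, phenotype
#' simulation, multi-seed training, attribution, MAS aggregation into
#' PAL, permuted-label null fitting, P-value estimation, the logistic
#' regression baseline, and simulation evaluation. Every stage reads its
#' inputs from, and writes its artifacts to, `config$out_dir`; a manifest
#' JSON with output hashes makes reruns auditable. All randomness derives
#' from `config$master_seed` via [derive_seed()], so a rerun with the
#' same configuration reproduces identical artifacts.
#'
#' @param stage One of `"simulate-genotypes"`, `"simulate-phenotype"`,
#'   `"train"`, `"attribute"`, `"aggregate"`, `"null-fit"`, `"pvalues"`,
#'   `"gwas-lr"`, `"evaluate"`, `"all"`.
#' @param config A config list or JSON path (see [read_run_config()]).
#' @return Invisibly, a list of produced artifact paths.
#' @export
run_stage <- function(stage = c("all", "simulate-genotypes",
                                "simulate-phenotype", "train", "attribute",
                                "aggregate", "null-fit", "pvalues",
                                "gwas-lr", "evaluate"),
                      config) {
  stage <- match.arg(stage)
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    stages <- c("simulate-genotypes", "simulate-phenotype", "train",
                "attribute", "aggregate", "null-fit", "pvalues",
                "gwas-lr", "evaluate")
    return(invisible(lapply(stages, run_stage, config = config)))
  }
  msg("stage %s (master seed %d)", stage, config$master_seed)
  fun <- switch(stage,
                "simulate-genotypes" = stage_simulate_genotypes,
                "simulate-phenotype" = stage_simulate_phenotype,
                "train" = stage_train,
                "attribute" = stage_attribute,
                "aggregate" = stage_aggregate,
                "null-fit" = stage_null_fit,
                "pvalues" = stage_pvalues,
                "gwas-lr" = stage_gwas_lr,
                "evaluate" = stage_evaluate)
  invisible(fun(config))
}

#' Command-line entry point
#'
#' Thin flag parser around [run_stage()], for use as
#' `Rscript -e 'palnn::palnn_cli()' -- --config cfg.json --stage all`.
#' Supported flags: `--config <path>` (required), `--stage <name>`
#' (default `all`), `--seed <int>` (overrides `master_seed`),
#' `--method {sm,ig,pm}`, `--theta {strict,relaxed,<float>}`,
#' `--models <m>`, `--reps <n>`, `--out <dir>` (overrides `out_dir`).
#'
#' @param args Character vector of flags (defaults to the command line).
#' @return Invisibly, the result of [run_stage()].
#' @export
palnn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  flag <- function(name, default = NULL) {
    i <- which(args == name)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cfg_path <- flag("--config")
  if (is.null(cfg_path)) stop("--config <path> is required")
  config <- read_run_config(cfg_path)
  if (!is.null(flag("--seed"))) config$master_seed <- as.integer(flag("--seed"))
  if (!is.null(flag("--method"))) config$method <- flag("--method")
  if (!is.null(flag("--theta"))) config$theta_percentile <- flag("--theta")
  if (!is.null(flag("--models"))) config$m <- as.integer(flag("--models"))
  if (!is.null(flag("--reps"))) config$n_reps <- as.integer(flag("--reps"))
  if (!is.null(flag("--out"))) config$out_dir <- flag("--out")
  config <- read_run_config(unclass(config))  # re-validate overrides
  invisible(run_stage(flag("--stage", "all"), config))
}

load_pipeline_genotypes <- function(config) {
  gp <- stage_path(config, "genotypes.traw")
  if (!is.null(config$genotypes$path)) {
    read_genotypes(config$genotypes$path,
                   config$genotypes$format %||% "auto")
  } else {
    read_genotypes(require_artifact(gp, "simulate-genotypes"), "traw")
  }
}

stage_simulate_genotypes <- function(config) {
  gen <- config$genotypes %||% list()
  if (!is.null(gen$path)) {
    msg("using external genotypes at %s; nothing to simulate", gen$path)
    return(character())
  }
  seed <- derive_seed(config$master_seed, "simulate-genotypes")
  g <- generate_genotypes(
    n_individuals = gen$n_individuals %||% 2000L,
    n_positions = gen$n_positions %||% 5000L,
    block_size = gen$block_size %||% 10L,
    haplotype_pool = gen$haplotype_pool %||% 8L,
    maf_range = unlist(gen$maf_range %||% c(0.05, 0.5)),
    bp_spacing = gen$bp_spacing %||% 5000L,
    seed = seed
  )
  out <- stage_path(config, "genotypes.traw")
  write_genotypes(g, out, "traw")
  write_manifest(config, "simulate-genotypes", list(out), seeds = seed)
  out
}

stage_simulate_phenotype <- function(config) {
  g <- load_pipeline_genotypes(config)
  sc <- config$scenario
  e <- assign_effects(g, sc$n_causal,
                      seed = derive_seed(config$master_seed, "assign-effects"))
  ps <- simulate_phenotypes(g, e, k = sc$k,
                            seed = derive_seed(config$master_seed, "phenotype-noise"),
                            case_fraction = sc$case_fraction %||% (1814 / 9139))
  pheno_path <- stage_path(config, "phenotypes.tsv")
  eff_path <- stage_path(config, "effects.json")
  write_phenotypes(ps, pheno_path)
  write_effect_spec(e, eff_path)
  write_manifest(config, "simulate-phenotype", list(pheno_path, eff_path))
  c(pheno_path, eff_path)
}

pipeline_model_seeds <- function(config, null = FALSE) {
  mcount <- if (null) config$m_null else config$m
  tag <- if (null) "null-model" else "model"
  vapply(seq_len(mcount), function(i) {
    derive_seed(config$master_seed, tag, i)
  }, integer(1))
}

stage_train <- function(config) {
  g <- load_pipeline_genotypes(config)
  ph <- read_phenotypes(require_artifact(stage_path(config, "phenotypes.tsv"),
                                         "simulate-phenotype"))
  labels <- as.integer(ph$y_binary)
  cfg <- model_config_from(config, ncol(g$values))
  dir.create(stage_path(config, "models"), showWarnings = FALSE)
  outs <- character()

  models <- train_ensemble(g, labels, cfg, seeds = pipeline_model_seeds(config))
  for (i in seq_along(models)) {
    p <- stage_path(config, "models", sprintf("model_%02d.rds", i))
    save_model(models[[i]], p)
    write_history(models[[i]], sub("\\.rds$", "_history.tsv", p))
    outs <- c(outs, p)
  }
  if (config$m_null > 0L) {
    nulls <- train_ensemble(g, labels, cfg,
                            seeds = pipeline_model_seeds(config, null = TRUE),
                            permute_labels = TRUE,
                            permutation_seed = derive_seed(config$master_seed,
                                                          "label-permutation"))
    for (i in seq_along(nulls)) {
      p <- stage_path(config, "models", sprintf("null_%02d.rds", i))
      save_model(nulls[[i]], p)
      outs <- c(outs, p)
    }
  }
  write_manifest(config, "train", as.list(outs),
                 seeds = list(models = pipeline_model_seeds(config),
                              null = pipeline_model_seeds(config, TRUE)))
  outs
}

pipeline_mas <- function(config, g, labels, prefix) {
  files <- sort(list.files(stage_path(config, "models"),
                           pattern = paste0("^", prefix, "_[0-9]+\\.rds$"),
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("missing upstream artifact: no '", prefix,
         "_*.rds' models found; run stage 'train' first")
  }
  models <- lapply(files, load_model)
  ensemble_mas(models, g, labels, method = config$method,
               drop_degenerate = TRUE, n_steps = config$n_steps,
               seed = derive_seed(config$master_seed, "attribution"))
}

stage_attribute <- function(config) {
  g <- load_pipeline_genotypes(config)
  ph <- read_phenotypes(require_artifact(stage_path(config, "phenotypes.tsv"),
                                         "simulate-phenotype"))
  labels <- as.integer(ph$y_binary)
  outs <- character()
  for (prefix in c("model", if (config$m_null > 0L) "null")) {
    mas_list <- pipeline_mas(config, g, labels, prefix)
    for (i in seq_along(mas_list)) {
      p <- stage_path(config, sprintf("mas_%s_%s_%02d.tsv",
                                      config$method, prefix, i))
      write_mas(mas_list[[i]], g, p)
      outs <- c(outs, p)
    }
  }
  write_manifest(config, "attribute", as.list(outs))
  outs
}

read_mas_files <- function(config, prefix) {
  files <- sort(list.files(config$out_dir,
                           pattern = sprintf("^mas_%s_%s_[0-9]+\\.tsv$",
                                             config$method, prefix),
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("missing upstream artifact: no MAS tables for '", prefix,
         "'; run stage 'attribute' first")
  }
  lapply(files, function(f) {
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
    structure(list(values = tab$mas, method = meta$method,
                   n_samples_averaged = meta$n_samples_averaged,
                   model_seed = meta$model_seed),
              class = "mas_vector")
  })
}

stage_aggregate <- function(config) {
  g <- load_pipeline_genotypes(config)
  Amat <- mas_matrix(read_mas_files(config, "model"))
  report <- aggregate_mas(Amat, q = config$theta_percentile)
  report <- finalize_pal(report, g, r_threshold = config$r_threshold)
  out <- stage_path(config, "pal_report.tsv")
  write_pal_report(report, g, out)
  saveRDS(report, stage_path(config, "pal_report.rds"))
  write_manifest(config, "aggregate", list(out))
  out
}

stage_null_fit <- function(config) {
  null_mas <- read_mas_files(config, "null")
  pooled <- pool_null_mas(null_mas)
  null <- fit_halfnormal(pooled)
  null$fit_table <- tryCatch(
    compare_tail_distributions(pooled, tail_quantile = 0.999),
    error = function(e) {
      message("tail comparison skipped: ", conditionMessage(e))
      NULL
    })
  out <- stage_path(config, "null_model.json")
  jsonlite::write_json(
    list(sigma = null$sigma, n_pooled = null$n_pooled,
         fit_table = null$fit_table),
    out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(null$fit_table)) {
    utils::write.table(null$fit_table, stage_path(config, "null_fit_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(config, "null-fit", list(out))
  out
}

stage_pvalues <- function(config) {
  g <- load_pipeline_genotypes(config)
  nm_path <- require_artifact(stage_path(config, "null_model.json"), "null-fit")
  nm <- jsonlite::read_json(nm_path, simplifyVector = TRUE)
  null <- structure(list(sigma = nm$sigma, n_pooled = nm$n_pooled,
                         fit_table = NULL),
                    class = "null_model")
  report <- readRDS(require_artifact(stage_path(config, "pal_report.rds"),
                                     "aggregate"))
  Amat <- mas_matrix(read_mas_files(config, "model"))
  pv <- estimate_pvalues(Amat, report, null, n_reps = config$n_reps,
                         seed = derive_seed(config$master_seed, "pvalues"))
  out <- stage_path(config, "pvalues.tsv")
  write_pvalues(pv, g, out)
  write_manifest(config, "pvalues", list(out))
  out
}

stage_gwas_lr <- function(config) {
  g <- load_pipeline_genotypes(config)
  ph <- read_phenotypes(require_artifact(stage_path(config, "phenotypes.tsv"),
                                         "simulate-phenotype"))
  covs <- pca_covariates(g, k = 3L)
  res <- logistic_gwas(g, as.integer(ph$y_binary), covariates = covs)
  out <- stage_path(config, "gwas_lr.tsv")
  utils::write.table(res$table, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_tested = res$n_tested, alpha = res$alpha,
         bonferroni_threshold = res$bonferroni_threshold),
    paste0(out, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(config, "gwas-lr", list(out))
  out
}

stage_evaluate <- function(config) {
  g <- load_pipeline_genotypes(config)
  e <- read_effect_spec(require_artifact(stage_path(config, "effects.json"),
                                         "simulate-phenotype"))
  report <- readRDS(require_artifact(stage_path(config, "pal_report.rds"),
                                     "aggregate"))
  out <- stage_path(config, "evaluation.json")
  pal_eval <- if (length(report$pal_amas) > 0L) {
    ev <- evaluate_detections(report$pal_amas, e, g)
    c(ev$metrics, list(per_class = as.list(ev$breakdown$per_class)))
  } else {
    list(precision = NULL, recall = 0, tp = 0L, fp = 0L,
         note = "empty PAL_AMAS set")
  }
  lr <- NULL
  lr_path <- stage_path(config, "gwas_lr.tsv")
  if (file.exists(lr_path)) {
    tab <- utils::read.delim(lr_path, stringsAsFactors = FALSE)
    thr <- 0.05 / nrow(tab)
    hits <- which(!is.na(tab$p) & tab$p < thr)
    lr <- if (length(hits) > 0L) {
      ev <- evaluate_detections(hits, e, g)
      ev$metrics
    } else {
      list(precision = NULL, recall = 0, tp = 0L, fp = 0L)
    }
  }
  jsonlite::write_json(list(pal = pal_eval, logistic_regression = lr),
                       out, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  write_manifest(config, "evaluate", list(out))
  out
}
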