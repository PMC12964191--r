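# Internal helpers shared across modules.

#' Derive a stage-specific random seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds from a single
#' master seed through this function, so that a run is fully reproducible
#' from one integer while stages remain statistically independent.
#'
#' @param master_seed Integer master seed.
#' @param stage Character scalar naming the consuming stage (hashed).
#' @param index Optional non-negative integer offset (e.g. model number).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, stage, index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  # 64-bit-free multiplicative hash kept inside double precision:
  # work modulo 2^31 - 1 with small multipliers.
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.numeric(index)) %% m
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Population (ddof = 0) variance.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
}
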