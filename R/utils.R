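# Internal helpers shared across modules.

#' Derive a reproducible per-key random seed
#'
#' Combines a master seed with a character key (typically a sample
#' identifier) into a deterministic 32-bit seed, so that every sample gets
#' its own random stream and adding samples to a cohort never perturbs the
#' draws of existing ones.
#'
#' @param master_seed integer master seed.
#' @param key character scalar (e.g. a sample id).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, key) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            length(key) == 1L)
  mod <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% mod
  as.integer(((as.numeric(master_seed) %% mod) * 48271 + h) %% mod)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic, locale-independent multi-key ordering (C collation).
order_c <- function(...) order(..., method = "radix", na.last = TRUE)

# Stop with a formatted message, no call in the condition.
stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
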