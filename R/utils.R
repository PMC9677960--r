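# Internal helpers: reproducible seed derivation, scoped RNG, light hashing.

#' Derive a child seed from a top-level seed
#'
#' All stochastic steps in the package draw their seed from one top-level
#' integer via this function, so any stage can be re-run in isolation and
#' reproduce exactly what a full pipeline run did. The derivation hashes the
#' textual tokens with a 31-multiplier rolling hash modulo 2^31 - 2, keeping
#' the result a valid 32-bit seed.
#'
#' @param seed integer top-level seed.
#' @param ... tokens (coerced to character) identifying the consuming stage,
#'   e.g. `derive_seed(7, "grid", ws, ss)`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483646 # 2^31 - 2
  h <- abs(as.numeric(seed)) %% m
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (tok in tokens) {
    for (k in utf8ToInt(tok)) {
      h <- (h * 31 + k) %% m
    }
  }
  as.integer(h) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used to stamp
# configuration provenance into output files without a digest dependency.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x))
  x <- paste(x, collapse = "\n")
  h <- 2166136261
  for (k in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), k) # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
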