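#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, then restores
#' the caller's RNG state. The generator kind is pinned (Mersenne-Twister,
#' Rejection sampling) so results are stable across R versions.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

#' Derive a child seed from a master seed and a string key
#'
#' Deterministic polynomial hash over the key's bytes, folded into the master
#' seed modulo 2^31 - 1. Guarantees the same (seed, key) pair always yields the
#' same child seed, so per-gene simulation is identical whether genes are
#' processed serially or independently.
#'
#' @param seed Integer master seed.
#' @param key Character scalar (e.g. a gene id).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- as.double(seed) %% m
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h + 1)
}

# Non-scientific formatting for deterministic table output.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

# FNV-1a 32-bit hash of a character scalar; used to fingerprint configs in
# report metadata without a hashing dependency.
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
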