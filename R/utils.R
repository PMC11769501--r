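# Shared internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps all package randomness isolated
# and reproducible.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of a master seed into sub-stream seeds, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    acc <- (acc * 69069 + as.numeric(p) * 7919 + 12345) %% 2147483629
  }
  as.integer(acc %% 2147483629) + 1L
}

# Cheap content checksum for equality diagnostics on numeric arrays.
num_checksum <- function(x) {
  v <- as.numeric(x)
  c(n = length(v), s1 = sum(v), s2 = sum(v * seq_along(v) %% 97))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
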