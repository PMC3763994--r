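# Internal helpers: reproducible per-sample RNG streams.
#
# Every randomised operation derives its own seed from a master seed plus a
# stable string hash of identifying tags (sample id, supercell size, ...), so
# adding a patient to a cohort never perturbs the supercells drawn for the
# others, and re-running with the same seed is bitwise reproducible.

# djb2-style polynomial string hash, kept inside 32-bit signed range
hash_string <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

derive_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  as.integer((as.numeric(master) %% 2147483647 + hash_string(tags)) %% 2147483647)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
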