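# Small internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so that simulators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) %% 1000000L) * 2013L + (h %% 1000L) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a
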