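# small internal utilities

# evaluate code under a given RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# derive a child seed from a base seed and stream index, below 2^31
derive_seed <- function(seed, stream) {
  ((as.double(seed) %% 2147483629) * 48271 + stream) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
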