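# Internal helpers.

# Run code with a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards so generators never perturb user RNG flow.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stage label, staying < 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 1009L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
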