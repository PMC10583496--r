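# Statistical-precondition failures carry their own condition class so the
# command-line wrapper can map them to a distinct exit code.
abort_stat <- function(message) {
  abort(message, class = "speechlex_stat_error")
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state
# afterwards so stochastic ops have no hidden global side effects.
with_preserved_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
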