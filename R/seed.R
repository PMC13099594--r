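# Seed plumbing: one user-facing integer seed drives every stochastic stage.
# Sub-seeds are derived deterministically (Knuth multiplicative hash mod the
# Mersenne prime 2^31 - 1) so stages can be re-run independently.

derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer(((abs(seed) + 1) * 2654435761 + 97 * offset) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  force(code)
}
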