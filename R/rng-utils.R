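# RNG plumbing: every stochastic operation takes an explicit seed, scopes
# it (caller's RNG state is untouched), and derives deterministic
# substreams for per-variant / per-replicate draws.

.saveRngState <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRngState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Derive a deterministic substream seed
#'
#' Maps a base seed and a stream index to a new seed via a multiplicative
#' congruential step modulo the Mersenne prime 2^31 - 1, so per-variant
#' and per-replicate draws are reproducible and mutually decoupled.
#'
#' @param seed base integer seed.
#' @param k stream index (>= 0).
#' @return integer seed in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, k) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (i in seq_len(k %% 64 + 1))
    s <- (s * 48271 + k + 1) %% m
  as.integer(if (s == 0) 1 else s)
}

# run code under a scoped seed
.withSeed <- function(seed, code) {
  old <- .saveRngState()
  on.exit(.restoreRngState(old))
  set.seed(seed)
  code
}
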