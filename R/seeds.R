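# Per-stream seed expansion: every generator derives its RNG seed from a
# single user-facing integer seed plus a fixed stream offset, so distinct
# generators driven by the same base seed produce independent, reproducible
# streams.  Kept below 2^31 - 1.
.stream_seed <- function(seed, stream) {
  offsets <- c(spectrum = 101L, brownian = 211L, confined = 307L,
               pressure = 401L, fit_start = 503L, eisf = 601L,
               workflow = 701L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

# evaluate `expr` under a local RNG state seeded from (seed, stream)
.with_stream_seed <- function(seed, stream, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(.stream_seed(seed, stream))
  expr
}
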