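## Run an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards so that seeded operations do not disturb the
## global stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Fan one user seed out into named substreams (values < 2^31) so that
## independent draws stay independent of how many other streams exist.
.substreams <- function(seed, names) {
  s <- .withSeed(seed, sample.int(.Machine$integer.max, length(names)))
  stats::setNames(as.integer(s), names)
}
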