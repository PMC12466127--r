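# Internal helpers shared across modules.

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state. All generators route their randomness through this so that
## every fixture is a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## round() uses banker's rounding; planted-count arithmetic needs the
## conventional "round half up" so realized counts match the recorded plan.
round_half_up <- function(x) as.integer(floor(x + 0.5))

## Single place that turns a parsed MUT cell / SNV row into its canonical
## "chrom:posREF>ALT" string.
snv_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d%s>%s", chrom, as.integer(pos), ref, alt)
}
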