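## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Truncated-at-zero normal draws (resampling; falls back to pmax after a cap
## for pathological parameter choices).
rnorm_pos <- function(n, mean, sd) {
  if (all(sd == 0)) return(pmax(rep_len(mean, n), 0))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    neg <- x < 0
    if (!any(neg)) break
    x[neg] <- stats::rnorm(sum(neg), rep_len(mean, n)[neg],
                           rep_len(sd, n)[neg])
  }
  pmax(x, 0)
}
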