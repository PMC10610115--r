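#' @include AllClasses.R
NULL

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))
  force(expr)
}

# Population (divide-by-n) z-score of a data.frame's numeric columns.
.zscorePop <- function(df) {
  as.data.frame(lapply(df, function(v) {
    mu <- mean(v); s <- sqrt(mean((v - mu)^2))
    if (s < .Machine$double.eps^0.5) s <- 1
    (v - mu) / s
  }))
}
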