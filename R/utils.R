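## evaluate expr under a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## deterministic assignment of n records to k near-equal folds
makeFolds <- function(n, k, seed) {
  withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

## column standardization that tolerates constant columns
standardizeFit <- function(m) {
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

standardizeApply <- function(m, std) {
  scale(m, center = std$center, scale = std$scale)[, , drop = FALSE]
}
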