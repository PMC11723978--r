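# Internal helpers: seeded substreams and small numerics.

# One root seed drives the whole pipeline; each stage draws from a named
# substream so stages are independently reproducible. The hash is a plain
# 31-bit multiplicative mix, stable across platforms.
substreamSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((seed %% 2147483647) * 48271 + h + 1) %% 2147483647)
}

# Evaluate fn() with a temporary RNG state seeded from (seed, stage),
# restoring the caller's RNG afterwards.
withSubstream <- function(seed, stage, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, stage))
  fn()
}

# Mean of matrix columns over a frame index set, tolerating a single frame.
frameMean <- function(mat, frames) {
  if (length(frames) == 1) mat[, frames] else rowMeans(mat[, frames,
                                                           drop = FALSE])
}

# Stratified fold assignment: within each class, cycle fold labels over a
# random permutation so folds are balanced.
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  fold
}
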