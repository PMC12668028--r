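## Internal helpers: seed streams and index bookkeeping.

# Evaluate expr with a temporary RNG seed, restoring .Random.seed after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive an independent substream seed (< 2^31) from a master seed and
# string/integer tags; a small multiplicative hash keeps streams for
# different (stage, n, replicate) tuples distinct.
deriveSeed <- function(master, ...) {
  tags <- list(...)
  acc <- as.double(master) %% 2147483563
  for (tg in tags) {
    if (is.character(tg)) tg <- sum(utf8ToInt(tg) * seq_along(utf8ToInt(tg)))
    acc <- (acc * 69069 + as.double(tg) + 1) %% 2147483563
  }
  as.integer(acc %% 2147483562 + 1)
}

# All unordered pairs (i < j), 1-based, lexicographic.
pairIndices <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  t(combn(n, 2L))
}

# All unordered triples (i < j < k), 1-based, lexicographic.
tripleIndices <- function(n) {
  if (n < 3) return(matrix(integer(0), 0, 3))
  t(combn(n, 3L))
}

pairVectorToMatrix <- function(v, n, diagValue = 0) {
  m <- matrix(0, n, n)
  idx <- pairIndices(n)
  m[idx] <- v
  m <- m + t(m)
  diag(m) <- diagValue
  m
}

# Row-lexicographic pair vector from a symmetric matrix.
pairVectorLex <- function(m) {
  idx <- pairIndices(nrow(m))
  m[idx]
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
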