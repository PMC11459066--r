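# Internal helpers shared across modules.

# Deterministic 31-bit seed derivation from a base seed plus stream labels.
# Multiplicative-congruential mixing in double precision; every intermediate
# stays below 2^53 so the arithmetic is exact. Used so that per-sample /
# per-role / per-run seeds are pure functions of (seed, labels) and appending
# samples or runs never changes earlier ones.
seedHash <- function(...) {
  h <- 17
  for (v in as.numeric(c(...))) {
    v <- abs(v) %% 2147483647
    h <- (h * 69069 + v + 1) %% 2147483647
    h <- (h * 48271 + 11) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

isBinary <- function(m) all(m %in% c(0, 1))

# Dice coefficient between two binary masks (logical or 0/1); the both-empty
# convention is an argument so callers can surface it explicitly.
diceBinary <- function(a, b, bothEmpty = 1) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(bothEmpty)
  2 * sum(a & b) / denom
}

# Stable content hash of a deparsed object, for run manifests.
contentHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  sprintf("%08x", seedHash(utf8ToInt(s)))
}

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
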