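# Independent scalar/loop oracles used to pin the vectorized implementations.

# 2x2 stride-2 max-pool, plain loops.
naivePool <- function(m) {
  H <- nrow(m) / 2; W <- ncol(m) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- max(m[2 * i - 1, 2 * j - 1], m[2 * i, 2 * j - 1],
                     m[2 * i - 1, 2 * j], m[2 * i, 2 * j])
  out
}

# 2x bilinear doubling with half-pixel centers and edge clamping, computed
# directly from the source-coordinate definition: output pixel i (0-based)
# samples input coordinate i/2 - 0.25.
naiveUpsample <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, 2 * H, 2 * W)
  tap <- function(n, i0) {            # 0-based output index -> taps/weights
    s <- i0 / 2 - 0.25
    lo <- floor(s); hi <- lo + 1
    wHi <- s - lo
    lo <- min(max(lo, 0), n - 1); hi <- min(max(hi, 0), n - 1)
    list(lo = lo + 1, hi = hi + 1, wLo = 1 - wHi, wHi = wHi)
  }
  for (i in 0:(2 * H - 1)) for (j in 0:(2 * W - 1)) {
    ti <- tap(H, i); tj <- tap(W, j)
    out[i + 1, j + 1] <-
      ti$wLo * (tj$wLo * m[ti$lo, tj$lo] + tj$wHi * m[ti$lo, tj$hi]) +
      ti$wHi * (tj$wLo * m[ti$hi, tj$lo] + tj$wHi * m[ti$hi, tj$hi])
  }
  out
}

naiveRemainder <- function(m) m - naiveUpsample(naivePool(m))

# Scalar-accumulation Hoyer-Square.
naiveHoyerSquare <- function(w) {
  s1 <- 0; s2 <- 0
  for (v in w) { s1 <- s1 + abs(v); s2 <- s2 + v * v }
  if (s2 == 0) 0 else s1 * s1 / s2
}

# Scalar-loop Dice loss.
naiveDiceLoss <- function(p, t, eps) {
  num <- 0; sp <- 0; st <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * t[i]; sp <- sp + p[i]; st <- st + t[i]
  }
  1 - (2 * num + eps) / (sp + st + eps)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# patterns (requires no zero differences and no tied |d|).
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  Vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  pLow <- mean(Vs <= V); pHigh <- mean(Vs >= V)
  min(1, 2 * min(pLow, pHigh))
}

# Integer-count masked Dice (binarize at 0.5), scalar loops; NA when no
# pixel is retained, 1 when both masks are empty on the retained set.
naiveMaskedDice <- function(p, g, keep) {
  nP <- 0L; nG <- 0L; nPG <- 0L; nKeep <- 0L
  for (i in seq_along(p)) {
    if (!keep[i]) next
    nKeep <- nKeep + 1L
    P <- p[i] >= 0.5; G <- g[i] == 1
    nP <- nP + P; nG <- nG + G; nPG <- nPG + (P && G)
  }
  if (nKeep == 0L) return(NA_real_)
  if (nP + nG == 0L) return(1)
  2 * nPG / (nP + nG)
}

# Connected-component count (4-neighbour flood fill), independent of
# EBImage's labeling.
countComponents <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nc <- 0L
  for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
    if (mask[i0, j0] != 1 || seen[i0, j0]) next
    nc <- nc + 1L
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        i <- ij[1] + d[1]; j <- ij[2] + d[2]
        if (i >= 1 && i <= H && j >= 1 && j <= W &&
            mask[i, j] == 1 && !seen[i, j]) {
          seen[i, j] <- TRUE
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  nc
}

# Plain Dice between binary masks.
plainDice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a * b) / s
}
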