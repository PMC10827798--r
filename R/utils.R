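# Internal numeric helpers shared across modules.

# Gaussian smoothing weight matrix for a 1-D axis of length n.  Row-stochastic
# after renormalization, so edges use truncated (replicate-equivalent) kernels.
.gaussWeights <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  k <- exp(-x^2 / (2 * sigma^2))
  W <- matrix(0, n, n)
  for (j in seq_along(x)) {
    idx <- seq_len(n) + x[j]
    ok <- idx >= 1 & idx <= n
    W[cbind(which(ok), idx[ok])] <- W[cbind(which(ok), idx[ok])] + k[j]
  }
  W / rowSums(W)
}

# Separable NA-aware Gaussian smoothing (normalized convolution): cells that
# are NA contribute zero weight, so the ragged lower margin of the choroid
# window does not bleed into valid pixels.  sigmaRow smooths along depth
# (down columns), sigmaCol along the lateral axis (along rows).
.gaussSmooth <- function(m, sigmaRow = 0, sigmaCol = 0) {
  valid <- !is.na(m)
  x <- m
  x[!valid] <- 0
  w <- valid * 1
  if (sigmaCol > 0) {
    Wc <- .gaussWeights(ncol(m), sigmaCol)
    x <- x %*% t(Wc)
    w <- w %*% t(Wc)
  }
  if (sigmaRow > 0) {
    Wr <- .gaussWeights(nrow(m), sigmaRow)
    x <- Wr %*% x
    w <- Wr %*% w
  }
  out <- x / w
  out[w <= 1e-12] <- NA_real_
  out[!valid] <- NA_real_
  out
}

.gaussSmooth1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  as.numeric(.gaussSmooth(matrix(v, ncol = 1), sigmaRow = sigma))
}

# Evaluate a quadratic row = a*col^2 + b*col + c.
.quadEval <- function(coef, cols) coef[1] * cols^2 + coef[2] * cols + coef[3]

# Run code with a fixed RNG state, restoring the caller's stream.
.withSeed <- function(seed, code) withr::with_seed(as.integer(seed) %% 2147483647L, code)

# Derive reproducible child seeds from a parent seed.
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(2147483646L, n))
}

# Subpixel location of the maximum of v near its discrete argmax, by
# quadratic interpolation of the three points around the peak.  Apply to
# abs(v), v or -v to locate absolute, rising or falling changes.
.subpixelPeak <- function(v) {
  i <- which.max(v)
  if (i <= 1 || i >= length(v)) return(i)
  y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
  den <- y0 - 2 * y1 + y2
  if (abs(den) < 1e-12) return(i)
  i + 0.5 * (y0 - y2) / den
}

# Orient a difference trace for peak search: +1 rising, -1 falling, 0 absolute.
.orient <- function(d1, direction) {
  if (direction > 0) d1 else if (direction < 0) -d1 else abs(d1)
}

# Lightweight FNV-1a style fingerprint of a configuration list, recorded in
# result files so outputs can be traced to the settings that produced them.
.configHash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
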