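# Independent brute-force oracles used to pin down expected values.
# These deliberately use explicit loops / definitional formulas and never
# call the package's own implementations.

# Pearson correlation by the definitional double loop.
oracle_pearson_matrix <- function(x) {
  q <- ncol(x)
  out <- matrix(0, q, q)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      a <- x[, i] - mean(x[, i])
      b <- x[, j] - mean(x[, j])
      out[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }
  }
  out
}

# Intrinsic-timescale estimator: full autocorrelation sequence by explicit
# double loops, summed up to the lag before the first sign change.
oracle_int <- function(y, tr) {
  n <- length(y)
  ybar <- mean(y)
  denom <- sum((y - ybar)^2)
  r <- numeric(n - 2)
  for (k in seq_len(n - 2)) {
    s <- 0
    for (t in (k + 1):n) s <- s + (y[t] - ybar) * (y[t - k] - ybar)
    r[k] <- s / denom
  }
  neg <- which(r < 0)
  nk <- if (length(neg) == 0) n - 2 else neg[1] - 1
  if (nk == 0) 0 else tr * sum(r[seq_len(nk)])
}

# Volume normalization + off-diagonal min-max, element by element.
oracle_normalize_sc <- function(raw, vol) {
  q <- nrow(raw)
  out <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(q))
    out[i, j] <- raw[i, j] / sqrt(vol[i] * vol[j])
  diag(out) <- 0
  off <- numeric(0)
  for (i in seq_len(q)) for (j in seq_len(q))
    if (i != j) off <- c(off, out[i, j])
  lo <- min(off); hi <- max(off)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    if (i != j) out[i, j] <- if (hi == lo) 0 else (out[i, j] - lo) / (hi - lo)
  }
  out
}

# Spearman by average ranks then the Pearson formula.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  ra <- ra - mean(ra); rb <- rb - mean(rb)
  sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2))
}

# Mask penalty by explicit elementwise loops.
oracle_mask_penalty <- function(m, l1, l2, l3) {
  q <- nrow(m)
  s1 <- 0; s2 <- 0
  for (i in seq_len(q)) for (j in seq_len(q)) {
    s1 <- s1 + abs(m[i, j]); s2 <- s2 + m[i, j]^2
  }
  e <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    acc <- 0
    for (k in seq_len(q)) acc <- acc + m[i, k] * m[j, k]
    e[i, j] <- acc - (i == j)
  }
  s3 <- 0
  for (i in seq_len(q)) for (j in seq_len(q)) s3 <- s3 + e[i, j]^2
  l1 * s1 + l2 * s2 + l3 * sqrt(s3)
}

# Manifold loss by the definitional double sum over neighbourhoods.
oracle_manifold <- function(h, a) {
  q <- nrow(a)
  tot <- 0
  for (i in seq_len(q)) for (j in seq_len(q)) {
    if (i != j && a[i, j] != 0) tot <- tot + sum((h[i, ] - h[j, ])^2)
  }
  tot / 2
}

# Dense evaluation of one masked graph-convolution layer.
oracle_masked_layer <- function(h, a, m, theta) {
  q <- nrow(a)
  at <- a + diag(q)
  d <- rowSums(at)
  s <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(q))
    s[i, j] <- at[i, j] / sqrt(d[i] * d[j])
  f <- (m + diag(q)) * s
  f %*% h %*% theta
}

rand_sym_graph <- function(q, density = 0.4) {
  a <- matrix(stats::runif(q * q), q)
  a[a > density] <- 0
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}
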