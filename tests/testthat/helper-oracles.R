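# Independent oracles, written from first principles (no package internals).

# Mirror reflection without repeating the edge sample: 1-based position p
# on an axis of length n.
reflect1 <- function(p, n) {
  if (n == 1L) return(1L)
  period <- 2L * (n - 1L)
  q <- (p - 1L) %% period
  if (q < n) q + 1L else 2L * n - 1L - q
}

# Brute-force 2-D correlation with a separable kernel given as row taps
# (applied down columns) and col taps (applied across rows), mirror border.
brute_corr2 <- function(m, taps_row, taps_col) {
  H <- nrow(m); W <- ncol(m)
  rr <- (length(taps_row) - 1L) %/% 2L
  rc <- (length(taps_col) - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in -rr:rr) for (b in -rc:rc) {
      s <- s + taps_row[a + rr + 1L] * taps_col[b + rc + 1L] *
        m[reflect1(i + a, H), reflect1(j + b, W)]
    }
    out[i, j] <- s
  }
  out
}

# Brute-force window sum of a matrix over an odd window at one pixel,
# mirror border.
brute_window_sum <- function(m, i, j, window) {
  r <- (window - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  s <- 0
  for (a in -r:r) for (b in -r:r)
    s <- s + m[reflect1(i + a, H), reflect1(j + b, W)]
  s
}

# Exhaustive Otsu search recomputing per-k cumulative moments with the
# same algebraic form as the implementation (prefix sums via sum()).
otsu_brute <- function(probs) {
  L <- length(probs)
  i <- 0:(L - 1L)
  muT <- sum(i * probs)
  curve <- rep(NA_real_, L)
  best_k <- NA_integer_; best <- -Inf
  for (k in 0:(L - 1L)) {
    w <- sum(probs[i <= k])
    mu <- sum(i[i <= k] * probs[i <= k])
    if (w * (1 - w) > 0) {
      curve[k + 1L] <- (muT * w - mu)^2 / (w * (1 - w))
      if (curve[k + 1L] > best) { best <- curve[k + 1L]; best_k <- k }
    }
  }
  list(k_star = best_k, curve = curve)
}

# The alternative algebraic form of the between-class variance.
sigma_b2_class_form <- function(probs, k) {
  L <- length(probs); i <- 0:(L - 1L)
  w0 <- sum(probs[i <= k]); w1 <- sum(probs[i > k])
  mu0 <- sum(i[i <= k] * probs[i <= k]) / w0
  mu1 <- sum(i[i > k] * probs[i > k]) / w1
  w0 * w1 * (mu0 - mu1)^2
}

# Construct a histogram object directly from counts (controlled levels).
hist_from_counts <- function(counts) {
  structure(
    list(counts = counts, probs = counts / sum(counts),
         L = length(counts), N = sum(counts),
         bin_edges = list(min = 0, max = length(counts) - 1,
                          L = length(counts)),
         mask = matrix(TRUE, 1L, sum(counts))),
    class = "flow_histogram"
  )
}

random_probs <- function(L) {
  x <- stats::rexp(L) * stats::rbinom(L, 1L, 0.7)
  if (sum(x) == 0) x[1L] <- 1
  x / sum(x)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# 90-degree clockwise rotation of a matrix.
rot_cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])
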