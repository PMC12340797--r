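# Independent oracles used across the suite. These re-derive expected values
# by brute force and must stay independent of the package implementation.

# threshold formula evaluated directly
oracle_threshold <- function(v, k = 1.5) {
  mu <- sum(v) / length(v)
  sigma <- sqrt(sum((v - mu)^2) / length(v))
  (max(v) - min(v)) - k * sigma
}

# per-pixel scan of the binarization rule on a masked region
oracle_foreground_count <- function(values, k = 1.5) {
  vp <- max(values) - values
  vpp <- vp - min(vp)
  thr <- oracle_threshold(vpp, k)
  n <- 0L
  for (v in vpp) if (v >= thr) n <- n + 1L
  n
}

# brute-force radial accumulation over every pixel
oracle_radial <- function(I, center, q_nyq, n_bins) {
  nr <- nrow(I); nc <- ncol(I)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  dq <- q_nyq / n_bins
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r <- sqrt((i - center[1])^2 + (j - center[2])^2)
    q <- r * q_nyq / (nc / 2)
    if (q > q_nyq) next
    b <- min(n_bins, floor(q / dq) + 1L)
    sums[b] <- sums[b] + I[i, j]
    counts[b] <- counts[b] + 1L
  }
  list(mean = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
       counts = counts)
}

# two-sided Fisher p by full enumeration of the conditional distribution,
# with the same relative tolerance on the "as extreme" comparison that the
# conditional exact test specifies
oracle_fisher_p <- function(a, b, cc, d) {
  r1 <- a + b; c1 <- a + cc; N <- a + b + cc + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  x <- max(0, r1 + c1 - N):min(r1, c1)
  dens <- stats::dhyper(x, c1, N - c1, r1)
  obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up computed by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
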