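# Independent, deliberately naive reference implementations used to verify
# the production code.  These stay loop-literal and share no code with R/.

# Approximate Entropy by explicit double loops over templates.
oracle_apen <- function(x, m = 2, r_factor = 0.15) {
  n <- length(x)
  r <- r_factor * sd(x)
  if (r == 0) return(0)
  phi <- function(mm) {
    nt <- n - mm + 1
    logC <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          dk <- abs(x[i + k] - x[j + k])
          if (dk > dmax) dmax <- dk
        }
        if (dmax <= r) cnt <- cnt + 1
      }
      logC[i] <- log(cnt / nt)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# Rescaled range at a single segment length d, written directly from the
# defining recipe: adjacent segments, per-segment mean/SD, accumulated
# deviations, range of the accumulation, averaged R/S over segments with
# positive SD.
oracle_rs_at_d <- function(x, d) {
  N <- length(x)
  M <- floor(N / d)
  vals <- c()
  for (m in seq_len(M)) {
    seg <- x[((m - 1) * d + 1):(m * d)]
    E <- mean(seg)
    S <- sd(seg)
    if (S <= 0) next
    X <- numeric(d)
    acc <- 0
    for (k in seq_len(d)) {
      acc <- acc + (seg[k] - E)
      X[k] <- acc
    }
    R <- max(X) - min(X)
    vals <- c(vals, R / S)
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

# Spike counts per window by direct interval membership.
oracle_window_counts <- function(ts, Tw, duration) {
  nw <- floor(duration / Tw + 1e-9)
  counts <- integer(nw)
  for (i in seq_len(nw)) {
    lo <- (i - 1) * Tw
    hi <- i * Tw
    counts[i] <- sum(ts + 1e-9 * Tw >= lo & ts + 1e-9 * Tw < hi)
  }
  counts
}

# Theoretical fGn autocovariance.
fgn_gamma <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}
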