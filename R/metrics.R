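#' Coefficient of variation of an ISI sequence
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' 0 for strictly periodic firing, ~1 for Poisson firing.
#'
#' @param isis an `isi_sequence`, `spike_train`, or numeric interval vector.
#' @return dimensionless CV.
#' @export
isi_cv <- function(isis) {
  iv <- as_intervals(isis)
  if (length(iv) < 2L) stop("CV requires at least 2 intervals")
  stats::sd(iv) / mean(iv)
}

#' Fraction of ISIs in a half-open range
#'
#' Proportion of intervals with `lo_ms <= ISI < hi_ms` (half-open bin),
#' e.g. the 0-8 ms burst range or the 19-21 ms first entrainment peak.
#'
#' @param isis an `isi_sequence`, `spike_train`, or numeric interval vector
#'   (seconds).
#' @param lo_ms,hi_ms range endpoints in milliseconds, `lo_ms < hi_ms`.
#' @return fraction in `[0, 1]`.
#' @examples
#' isi_fraction(c(0.005, 0.020, 0.040), 0, 8) # 1/3
#' @export
isi_fraction <- function(isis, lo_ms, hi_ms) {
  if (!(lo_ms < hi_ms)) stop("`lo_ms` must be smaller than `hi_ms`")
  ms <- as_intervals(isis) * 1000
  mean(ms >= lo_ms & ms < hi_ms)
}

#' Probability-normalised ISI histogram
#'
#' Histogram of the ISI distribution on half-open bins `[lo, hi)` in
#' milliseconds.  Bins are centred on integer multiples of the bin width
#' (the first bin is `[-w/2, w/2)`), so a peak at an entrainment period of
#' n x 20 ms falls inside a single bin instead of straddling an edge.
#' Probabilities sum to 1 over the counted intervals; the bin centre of the
#' highest-probability bin is reported as the dominant peak (ties broken
#' toward the shortest ISI).
#'
#' @param isis an `isi_sequence`, `spike_train`, or numeric interval vector.
#' @param bin_width_ms bin width in milliseconds (default 1).
#' @param max_isi_ms upper edge of the last bin; defaults to cover the
#'   longest interval.
#' @return an `isi_histogram`: list with `bin_edges` (ms), `bin_centers`,
#'   `bin_probabilities`, `bin_width`, `dominant_peak_ms` and `n`.
#' @export
isi_histogram <- function(isis, bin_width_ms = 1, max_isi_ms = NULL) {
  if (bin_width_ms <= 0) stop("`bin_width_ms` must be positive")
  ms <- as_intervals(isis) * 1000
  if (is.null(max_isi_ms)) {
    max_isi_ms <- bin_width_ms * ceiling(max(ms) / bin_width_ms + 1e-12)
  }
  edges <- seq(-bin_width_ms / 2, max_isi_ms + bin_width_ms / 2,
               by = bin_width_ms)
  idx <- findInterval(ms, edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx <= length(edges) - 1L] # drop ISIs beyond range
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  probs <- counts / length(ms)
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  structure(
    list(bin_edges = edges, bin_centers = centers,
         bin_probabilities = probs, bin_width = bin_width_ms,
         dominant_peak_ms = centers[which.max(probs)], n = length(ms)),
    class = "isi_histogram"
  )
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("<isi_histogram> %d intervals, %d bins of %.3g ms; dominant peak at %.3g ms\n",
              x$n, length(x$bin_probabilities), x$bin_width,
              x$dominant_peak_ms))
  invisible(x)
}

#' Approximate Entropy of an ISI sequence
#'
#' Classic ApEn (with self-matches, not sample entropy): with templates of
#' length `m` compared under the Chebyshev (maximum-coordinate) distance at
#' tolerance `r`,
#' \deqn{ApEn = \Phi^m(r) - \Phi^{m+1}(r), \quad
#'       \Phi^m(r) = \frac{1}{N-m+1}\sum_i \log C_i^m(r),}
#' where \eqn{C_i^m(r)} is the fraction of templates within distance `r` of
#' template `i`.  Low values indicate regular (predictable) sequences; high
#' values indicate irregularity.  The tolerance is relative to amplitude:
#' `r = r_factor * SD` of the analysed sequence (sample SD, n - 1
#' denominator), the standard convention for ApEn of physiological series.
#'
#' For a constant sequence the relative tolerance degenerates to `r = 0`;
#' all templates are then identical and ApEn is defined as 0.
#'
#' @param isis an `isi_sequence`, `spike_train`, or numeric vector.
#' @param embedding_m template length m (default 2).
#' @param r_factor tolerance as a multiple of the sequence SD (default 0.15).
#' @return ApEn in nats (>= 0 up to numerical round-off).
#' @examples
#' apen(rep(c(1, 2), 50))            # near 0: perfectly alternating
#' apen(runif(200))                  # larger: irregular
#' @export
apen <- function(isis, embedding_m = 2, r_factor = 0.15) {
  x <- as_intervals(isis)
  m <- as.integer(embedding_m)
  if (m < 1L) stop("`embedding_m` must be >= 1")
  if (r_factor <= 0) stop("`r_factor` must be positive")
  n <- length(x)
  if (n < m + 2L) stop("ApEn requires at least embedding_m + 2 observations")
  r <- r_factor * stats::sd(x)
  if (r == 0) return(0) # constant sequence: all templates identical
  # Chebyshev distances built once from the scalar distance matrix, then
  # max-composed over the template window.
  d1 <- abs(outer(x, x, "-"))
  phi <- function(mm) {
    nt <- n - mm + 1L
    dm <- d1[seq_len(nt), seq_len(nt), drop = FALSE]
    if (mm > 1L) {
      for (k in seq_len(mm - 1L)) {
        dm <- pmax(dm, d1[k + seq_len(nt), k + seq_len(nt), drop = FALSE])
      }
    }
    ci <- rowSums(dm <= r) / nt # self-match included
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}
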