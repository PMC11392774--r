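#' Rescaled-range (R/S) curve of an ISI sequence
#'
#' For each segment length `d` on a log-spaced integer grid from `d_min`
#' (default 4) to `floor(N * d_max_fraction)` (default N/3), the first
#' `M * d` intervals (`M = floor(N / d)`) are split into `M` adjacent
#' segments.  Per segment `m` the mean `E_m` and sample SD `S_m` are
#' computed, the accumulated deviations
#' \deqn{X_{k,m} = \sum_{i \le k} (ISI_{i,m} - E_m)}
#' give the range \eqn{R_m = \max_k X_{k,m} - \min_k X_{k,m}}, and
#' \deqn{(R/S)_d = \frac{1}{M}\sum_m R_m / S_m.}
#' Segments with `S_m = 0` are excluded from the average (their count is
#' reported); a `d` whose segments are all degenerate is dropped.
#'
#' The trailing `N - M*d` intervals are discarded at each `d`.  The Hurst
#' exponent is fitted immediately (see [hurst_exponent()]): `H = 0.5` for
#' independent ISIs, `H > 0.5` persistent, `H < 0.5` antipersistent.
#'
#' @param isis an `isi_sequence`, `spike_train`, or numeric interval vector
#'   with at least 12 intervals (so the grid reaches `d = 4`).
#' @param d_min smallest segment length (default 4).
#' @param d_max_fraction largest segment length as a fraction of N
#'   (default 1/3).
#' @param n_points target number of grid points (default 15).
#' @param fit logical; fit H by OLS on double-log axes (default TRUE).
#' @return an `rs_curve`: list with `d_grid`, `RS_values`, `segments_used`,
#'   `segments_dropped`, `N`, and after fitting `H`, `fit_r2`.
#' @examples
#' x <- rlnorm(512)               # independent ISIs
#' rs_curve(x)$H                  # ~0.5
#' @export
rs_curve <- function(isis, d_min = 4, d_max_fraction = 1 / 3,
                     n_points = 15, fit = TRUE) {
  x <- as_intervals(isis)
  N <- length(x)
  if (N < 12L) stop("rescaled-range analysis requires at least 12 intervals")
  d_max <- floor(N * d_max_fraction)
  if (d_max < d_min) stop("`d_max_fraction` leaves no admissible segment length")
  d_grid <- unique(round(exp(seq(log(d_min), log(d_max),
                                 length.out = n_points))))
  d_grid <- d_grid[d_grid >= d_min & d_grid <= d_max]
  rs <- rep(NA_real_, length(d_grid))
  used <- integer(length(d_grid))
  dropped <- integer(length(d_grid))
  for (i in seq_along(d_grid)) {
    d <- d_grid[i]
    M <- floor(N / d)
    seg <- matrix(x[seq_len(M * d)], nrow = d)
    E <- colMeans(seg)
    S <- apply(seg, 2L, stats::sd)
    dev <- sweep(seg, 2L, E)
    X <- apply(dev, 2L, cumsum)
    if (d == 1L) X <- matrix(X, nrow = 1L)
    R <- apply(X, 2L, max) - apply(X, 2L, min)
    ok <- S > 0
    used[i] <- sum(ok)
    dropped[i] <- sum(!ok)
    if (any(ok)) rs[i] <- mean(R[ok] / S[ok])
  }
  keep <- !is.na(rs)
  if (!any(keep)) stop("all segment lengths degenerate (zero-variance segments)")
  curve <- structure(
    list(d_grid = d_grid[keep], RS_values = rs[keep],
         segments_used = used[keep], segments_dropped = dropped[keep],
         N = N, H = NA_real_, fit_r2 = NA_real_),
    class = "rs_curve"
  )
  if (fit) {
    if (length(curve$d_grid) < 4L) {
      stop("fewer than 4 usable segment lengths; cannot fit H")
    }
    f <- ols_slope(log10(curve$d_grid), log10(curve$RS_values))
    curve$H <- f$slope
    curve$fit_r2 <- f$r2
  }
  curve
}

#' Rescaled-range Hurst exponent
#'
#' OLS slope of `log10 (R/S)_d` against `log10 d` over the full segment-length
#' grid of an [rs_curve()].  Accepts a fitted curve or raw intervals (a curve
#' is built with defaults).  Estimates slightly outside `[0, 1]` are reported
#' as-is, not clipped.
#'
#' @param x an `rs_curve`, `isi_sequence`, `spike_train`, or numeric vector.
#' @return the Hurst exponent estimate (dimensionless).
#' @export
hurst_exponent <- function(x) {
  curve <- if (inherits(x, "rs_curve")) x else rs_curve(x, fit = TRUE)
  if (is.na(curve$H)) {
    if (length(curve$d_grid) < 4L) {
      stop("fewer than 4 usable segment lengths; cannot fit H")
    }
    f <- ols_slope(log10(curve$d_grid), log10(curve$RS_values))
    curve$H <- f$slope
  }
  curve$H
}

#' @export
print.rs_curve <- function(x, ...) {
  cat(sprintf("<rs_curve> %d segment lengths in [%d, %d] of N = %d intervals\n",
              length(x$d_grid), min(x$d_grid), max(x$d_grid), x$N))
  if (!is.na(x$H)) cat(sprintf("  H = %.3f (R^2 = %.3f)\n", x$H, x$fit_r2))
  invisible(x)
}

#' Write an R/S curve to CSV with a JSON sidecar
#'
#' CSV columns: `d`, `RS`, `M_used`; the sidecar `<path>.json` records the
#' fitted Hurst exponent, goodness of fit, and interval count.
#'
#' @param curve an `rs_curve`.
#' @param path CSV output path.
#' @export
write_rs_csv <- function(curve, path) {
  stopifnot(inherits(curve, "rs_curve"))
  utils::write.csv(data.frame(d = curve$d_grid, RS = curve$RS_values,
                              M_used = curve$segments_used),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(H = curve$H, fit_r2 = curve$fit_r2, N = curve$N),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
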