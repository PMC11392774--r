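# Fano-factor curve and scaling exponent.

test_that("hand-computed Fano factor: counts [2, 4, 3, 3] give F = 2/9", {
  # place spikes so the four 1-s windows of a 4-s record hold 2, 4, 3, 3
  ts <- c(0.1, 0.5,
          1.1, 1.3, 1.5, 1.7,
          2.2, 2.5, 2.8,
          3.1, 3.5, 3.9)
  tr <- spike_train(ts, duration = 4)
  fc <- fano_curve(tr, t_min = 1, t_max = 2, points_per_decade = 10,
                   fit = FALSE)
  expect_true(1 %in% fc$T_grid)
  # mean 3, sample variance 2/3 => F = 0.2222
  expect_equal(fc$F_values[fc$T_grid == 1], 2 / 9, tolerance = 1e-12)
})

test_that("window counts match the direct-membership oracle on random trains", {
  set.seed(20)
  for (rep in 1:100) {
    dur <- runif(1, 2, 20)
    ts <- sort(runif(rpois(1, 40) + 2, 0, dur))
    ts <- unique(ts)
    Tw <- runif(1, 0.2, dur / 4)
    nw <- floor(dur / Tw + 1e-9)
    idx <- floor(ts / Tw + 1e-9)
    counts <- tabulate(idx[idx < nw] + 1L, nbins = nw)
    expect_identical(counts, oracle_window_counts(ts, Tw, dur))
  }
})

test_that("Poisson control: F(T) ~ 1 across the grid, alpha ~ 0", {
  Fbar <- rowMeans(sapply(1:10, function(s) {
    fano_curve(generate_poisson(20, 60, seed = s), fit = FALSE)$F_values
  }))
  expect_true(all(abs(Fbar - 1) < 0.25))
  alphas <- sapply(1:10, function(s) {
    fano_curve(generate_poisson(20, 60, seed = s))$alpha
  })
  ci <- t.test(alphas)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("strictly periodic train: F = 0 at window sizes that are multiples of the period", {
  tr <- generate_periodic(0.02, 60, jitter_sd = 0)
  fc <- fano_curve(tr, fit = FALSE)
  mult <- fc$T_grid[abs(fc$T_grid / 0.02 - round(fc$T_grid / 0.02)) < 1e-9]
  expect_gt(length(mult), 2)
  expect_true(all(fc$F_values[fc$T_grid %in% mult] == 0))
})

test_that("an exact power-law curve recovers its exponent to numerical precision", {
  grid <- 10^seq(-1, 1, length.out = 21)
  curve <- structure(list(T_grid = grid, F_values = 2 * grid^0.8,
                          n_windows = rep(10L, 21), n_spikes = 1000L,
                          duration = 60, alpha = NA_real_,
                          fit_range = c(NA_real_, NA_real_),
                          fit_r2 = NA_real_),
                     class = "fano_curve")
  fitted <- fano_alpha(curve, fit_lo = 0.1, fit_hi = 10)
  expect_equal(fitted$alpha, 0.8, tolerance = 1e-10)
  expect_equal(fitted$fit_r2, 1, tolerance = 1e-10)
})

test_that("F(T) is invariant to a time shift by an exact multiple of T", {
  tr <- generate_poisson(20, 60, seed = 33)
  Tw <- 0.5
  k <- 20 # shift by k*T = 10 s within a longer record
  shifted <- spike_train(tr$timestamps + k * Tw, duration = 60 + k * Tw)
  f_of <- function(train) {
    fc <- fano_curve(train, t_min = Tw, t_max = 2, points_per_decade = 10,
                     fit = FALSE)
    fc$F_values[abs(fc$T_grid - Tw) < 1e-12]
  }
  # same spikes, windows realigned by a whole number of windows: the counts
  # of the original windows reappear, plus k empty leading windows
  idx0 <- floor(tr$timestamps / Tw + 1e-9)
  c0 <- tabulate(idx0[idx0 < 120] + 1L, nbins = 120)
  idx1 <- floor(shifted$timestamps / Tw + 1e-9)
  c1 <- tabulate(idx1[idx1 < 140] + 1L, nbins = 140)
  expect_identical(c1[(k + 1):140], c0)
})

test_that("fano_curve input validation and degenerate grids", {
  expect_error(fano_curve(spike_train(numeric(0), duration = 60)), "empty")
  tr <- generate_poisson(20, 60, seed = 1)
  expect_error(fano_curve(tr, t_min = 1, t_max = 0.5), "smaller")
  expect_error(fano_curve(tr, t_max = 100), "duration")
  # too few usable points in the fit range
  fc <- fano_curve(tr, fit = FALSE)
  expect_error(fano_alpha(fc, fit_lo = 9, fit_hi = 10), "fewer than 4")
})

test_that("shuffling a correlated train flattens the Fano curve", {
  tr <- generate_fractal_isi_train(fractal_train_config(
    target_H = 0.85, mean_isi = 0.02, isi_dispersion = 1,
    n_spikes = 2048, seed = 6))
  alpha_orig <- fano_curve(tr, t_max = min(10, tr$duration / 4))$alpha
  alphas_sur <- sapply(1:10, function(s) {
    iv <- shuffle_surrogate(to_isi(tr), seed = s)$intervals
    ts <- c(0, cumsum(iv))
    str <- spike_train(ts, duration = ts[length(ts)])
    fano_curve(str, t_max = min(10, str$duration / 4))$alpha
  })
  expect_lt(abs(mean(alphas_sur)), 0.15)
  expect_gt(alpha_orig, mean(alphas_sur) + 0.1)
})
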