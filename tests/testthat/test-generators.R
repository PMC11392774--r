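# Spike-train generators: Poisson and periodic controls, fractal ISI trains,
# entrained trains, baseline models, shuffle surrogates.

test_that("Poisson generator: count, CV of ISIs, determinism, errors", {
  expect_error(generate_poisson(-1, 60), "positive")
  expect_error(generate_poisson(20, 0), "positive")
  tr <- generate_poisson(20, 60, seed = 1)
  # expected count 1200; 99% Poisson interval
  expect_gt(n_spikes(tr), qpois(0.005, 1200))
  expect_lt(n_spikes(tr), qpois(0.995, 1200))
  expect_identical(generate_poisson(20, 60, seed = 5)$timestamps,
                   generate_poisson(20, 60, seed = 5)$timestamps)
  # exponential ISIs have CV = 1 analytically
  cvs <- sapply(1:20, function(s) isi_cv(generate_poisson(20, 60, seed = s)))
  expect_lt(abs(mean(cvs) - 1), 0.05)
})

test_that("periodic generator: exact construction and jitter coverage", {
  tr <- generate_periodic(0.02, 60, jitter_sd = 0)
  expect_equal(n_spikes(tr), 3001L) # spikes at 0, 0.02, ..., 60
  expect_true(all(abs(to_isi(tr)$intervals - 0.02) < 1e-12))
  expect_equal(isi_cv(tr), 0)
  expect_error(generate_periodic(60, 60), "smaller than")

  # with per-spike jitter SD 1 ms, the ISI is period + N(0, sqrt(2) ms);
  # the analytic mass of the [19, 21) ms bin is 2*pnorm(1/sqrt(2)) - 1
  frac <- mean(sapply(1:10, function(s) {
    isi_fraction(generate_periodic(0.02, 60, jitter_sd = 0.001, seed = s),
                 19, 21)
  }))
  expected <- 2 * pnorm(1 / sqrt(2)) - 1 # 0.5205
  expect_lt(abs(frac - expected), 0.03)
  # and it is the single dominant peak region of the histogram
  h <- isi_histogram(generate_periodic(0.02, 60, jitter_sd = 0.001, seed = 1),
                     bin_width_ms = 1)
  expect_equal(h$dominant_peak_ms, 20)
})

test_that("fractal ISI train follows the lognormal-fGn construction", {
  cfg <- fractal_train_config(target_H = 0.7, mean_isi = 0.05,
                              isi_dispersion = 0.8, n_spikes = 1024, seed = 3)
  tr <- generate_fractal_isi_train(cfg)
  expect_equal(n_spikes(tr), 1024L)
  isis <- to_isi(tr)$intervals
  expect_true(all(isis > 0))
  # exact reconstruction from the same fGn draw
  g <- generate_fgn(1023, 0.7, seed = 3)
  expect_equal(isis, 0.05 * exp(0.8 * g - 0.8^2 / 2), tolerance = 1e-12)
  expect_equal(tr$duration, tr$timestamps[length(tr$timestamps)])
  # degenerate dispersion gives a strictly periodic train
  tr0 <- generate_fractal_isi_train(fractal_train_config(
    target_H = 0.5, mean_isi = 0.01, isi_dispersion = 0, n_spikes = 100))
  expect_true(all(abs(to_isi(tr0)$intervals - 0.01) < 1e-15))
})

test_that("entrained train: exact periodic limit, marginal rate, ISI peaks", {
  # p = 1 with zero jitter: one spike per cycle, all ISIs exactly one period
  tr1 <- generate_entrained_train(entrainment_config(
    per_cycle_probability = 1, phase_jitter_sd = 0, duration = 60, seed = 1))
  expect_equal(n_spikes(tr1), 3000L)
  expect_true(all(abs(to_isi(tr1)$intervals - 0.02) < 1e-9))
  expect_error(generate_entrained_train(entrainment_config(
    per_cycle_probability = 0)), "empty")

  # marginal rate: with independent skipping (failure_H = 0.5) the spike
  # count lies in the binomial 99% interval of p; correlated skipping keeps
  # the same marginal p but overdisperses the count, so the interval check
  # is only valid in the independent case
  for (s in 1:5) {
    tr <- generate_entrained_train(entrainment_config(
      per_cycle_probability = 0.65, failure_H = 0.5, duration = 60, seed = s))
    expect_gt(n_spikes(tr), qbinom(0.005, 3000, 0.65))
    expect_lt(n_spikes(tr), qbinom(0.995, 3000, 0.65))
  }

  # mean rate over seeds ~ p * f = 32.5 spikes/s (correlated default)
  rates <- sapply(1:10, function(s) firing_rate(generate_entrained_train(
    entrainment_config(per_cycle_probability = 0.65, duration = 60, seed = s))))
  expect_lt(abs(mean(rates) - 32.5), 2.5)

  # ISI histogram: dominant peak at 20 ms, secondary mass at 40 and 60 ms
  tr <- generate_entrained_train(entrainment_config(
    per_cycle_probability = 0.65, phase_jitter_sd = 0.001,
    duration = 60, seed = 11))
  h <- isi_histogram(tr, bin_width_ms = 1)
  expect_equal(h$dominant_peak_ms, 20)
  p_at <- function(center) h$bin_probabilities[match(center, h$bin_centers)]
  expect_gt(p_at(40), p_at(30))
  expect_gt(p_at(60), p_at(50))
})

test_that("baseline generators hit their target rates and burst structure", {
  rates_p <- sapply(1:8, function(s) firing_rate(
    generate_baseline_train("pyramidal", seed = s)))
  expect_lt(abs(mean(rates_p) - 2.5), 0.8)
  rates_i <- sapply(1:8, function(s) firing_rate(
    generate_baseline_train("interneuron", seed = s)))
  expect_lt(abs(mean(rates_i) - 9), 2)
  # burst fraction ~ fraction of ISIs below 8 ms for pyramidal cells
  fb <- mean(sapply(1:8, function(s) isi_fraction(
    generate_baseline_train("pyramidal", seed = s), 0, 8)))
  expect_lt(abs(fb - 0.35), 0.10)
  # interneuron baseline is scattered: little mass below 8 ms
  fi <- mean(sapply(1:8, function(s) isi_fraction(
    generate_baseline_train("interneuron", seed = s), 0, 8)))
  expect_lt(fi, 0.15)
})

test_that("all generators are deterministic under a fixed seed", {
  gens <- list(
    function(s) generate_poisson(15, 30, seed = s)$timestamps,
    function(s) generate_periodic(0.02, 30, jitter_sd = 0.002, seed = s)$timestamps,
    function(s) generate_fractal_isi_train(fractal_train_config(
      n_spikes = 256, seed = s))$timestamps,
    function(s) generate_entrained_train(entrainment_config(
      duration = 30, seed = s))$timestamps,
    function(s) generate_baseline_train("pyramidal", seed = s)$timestamps,
    function(s) shuffle_surrogate(1:50 / 10, seed = s)$intervals
  )
  for (g in gens) {
    expect_identical(g(123), g(123))
  }
})

test_that("shuffle surrogate preserves the ISI multiset and moments", {
  tr <- generate_fractal_isi_train(fractal_train_config(
    target_H = 0.8, n_spikes = 512, seed = 4))
  isis <- to_isi(tr)
  sur <- shuffle_surrogate(isis, seed = 9)
  expect_equal(sort(sur$intervals), sort(isis$intervals))
  expect_equal(sur$mean_isi, isis$mean_isi)
  expect_equal(sur$sd_isi, isis$sd_isi)
  expect_equal(sur$cv, isis$cv)
  expect_false(identical(sur$intervals, isis$intervals))
  expect_error(shuffle_surrogate(1.5), "at least 2")
})
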