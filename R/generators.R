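#' Fractional Gaussian noise by circulant embedding
#'
#' Exact-in-distribution synthesis of zero-mean, unit-variance fractional
#' Gaussian noise (fGn) with Hurst exponent `H`, using the Davies-Harte
#' circulant embedding of the target autocovariance
#' \deqn{\gamma(k) = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right).}
#' Unlike recursive-filter approximations, the sampled sequence has exactly
#' this autocovariance.  `H = 0.5` reduces to white Gaussian noise; `H > 0.5`
#' gives persistent (positively long-range-correlated) noise, `H < 0.5`
#' antipersistent noise.
#'
#' @param n number of samples (>= 2).
#' @param H Hurst exponent, strictly between 0 and 1.
#' @param seed optional integer seed; the global RNG state is restored on exit.
#' @return numeric vector of length `n`.
#' @examples
#' g <- generate_fgn(1024, H = 0.8, seed = 1)
#' @export
generate_fgn <- function(n, H, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L || n != round(n)) {
    stop("`n` must be an integer >= 2")
  }
  if (!is.numeric(H) || length(H) != 1L || H <= 0 || H >= 1) {
    stop("`H` must lie strictly inside (0, 1)")
  }
  n <- as.integer(n)
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * n
  # circulant first row: gamma(0..n), then mirrored gamma(n-1..1)
  lam <- Re(stats::fft(c(gam, gam[n:2])))
  if (min(lam) < -1e-8 * max(lam)) {
    stop("circulant embedding is not positive semi-definite for n = ", n,
         ", H = ", H)
  }
  lam[lam < 0] <- 0
  with_seed(seed, {
    z_re <- stats::rnorm(n + 1L)
    z_im <- stats::rnorm(n - 1L)
    v <- complex(length.out = m)
    v[1L] <- sqrt(lam[1L]) * z_re[1L]
    v[n + 1L] <- sqrt(lam[n + 1L]) * z_re[n + 1L]
    v[2:n] <- sqrt(lam[2:n] / 2) * complex(real = z_re[2:n], imaginary = z_im)
    v[(n + 2L):m] <- Conj(v[n:2])
    Re(stats::fft(v))[1:n] / sqrt(m)
  })
}

#' Homogeneous Poisson spike train
#'
#' ISIs are i.i.d. exponential with mean `1/rate`; the Fano factor of such a
#' train is ~1 at every window size and its ISI Hurst exponent is ~0.5, which
#' makes it the reference "no long-range correlation" control.
#'
#' @param rate mean firing rate in spikes/s (> 0).
#' @param duration record length in seconds (> 0).
#' @param seed optional integer seed.
#' @inheritParams spike_train
#' @return a `spike_train`.
#' @export
generate_poisson <- function(rate, duration = 60, seed = NULL,
                             condition = "baseline",
                             cell_type = "unspecified", unit_id = "poisson") {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (spikes/s)")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a single positive number (seconds)")
  }
  ts <- with_seed(seed, {
    # draw ISIs in chunks until the record is covered
    acc <- numeric(0)
    total <- 0
    repeat {
      chunk <- stats::rexp(max(64L, ceiling(rate * duration * 0.25)), rate)
      acc <- c(acc, chunk)
      total <- total + sum(chunk)
      if (total > duration) break
    }
    t <- cumsum(acc)
    t[t <= duration]
  })
  spike_train(ts, duration = duration, condition = condition,
              cell_type = cell_type, unit_id = unit_id)
}

#' Periodic spike train with optional Gaussian timing jitter
#'
#' Spikes at `k * period + jitter` for `k = 0, 1, 2, ...`, clipped to
#' `[0, duration]`.  With `jitter_sd = 0` the train is strictly periodic
#' (CV of ISIs = 0, Fano factor 0 at window sizes that are multiples of the
#' period).
#'
#' @param period firing period in seconds (> 0, < duration).
#' @param duration record length in seconds.
#' @param jitter_sd SD in seconds of the Gaussian jitter applied per spike.
#' @param seed optional integer seed.
#' @inheritParams spike_train
#' @return a `spike_train`.
#' @export
generate_periodic <- function(period, duration = 60, jitter_sd = 0,
                              seed = NULL, condition = "baseline",
                              cell_type = "unspecified", unit_id = "periodic") {
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("`period` must be a single positive number (seconds)")
  }
  if (!is.numeric(jitter_sd) || length(jitter_sd) != 1L || jitter_sd < 0) {
    stop("`jitter_sd` must be >= 0")
  }
  if (period >= duration) {
    stop("`period` must be smaller than `duration` (need at least 2 spikes)")
  }
  base <- seq(0, duration, by = period)
  ts <- if (jitter_sd > 0) {
    t <- with_seed(seed, base + stats::rnorm(length(base), 0, jitter_sd))
    t <- sort(t[t >= 0 & t <= duration])
    t[c(TRUE, diff(t) > 0)] # drop exact ties (probability zero, defensive)
  } else {
    base
  }
  spike_train(ts, duration = duration, condition = condition,
              cell_type = cell_type, unit_id = unit_id)
}

#' Configuration for a fractal (long-range-correlated) ISI train
#'
#' Parameter bundle for [generate_fractal_isi_train()].  The ISI sequence is a
#' lognormal transform of fractional Gaussian noise: positivity is guaranteed
#' and the Hurst exponent of the driving noise is approximately preserved by
#' the monotone transform.
#'
#' @param target_H Hurst exponent of the driving fGn, in (0, 1).
#' @param mean_isi mean inter-spike interval in seconds (> 0).
#' @param isi_dispersion log-scale spread (dimensionless, >= 0); 0 gives a
#'   strictly periodic train with period `mean_isi`.
#' @param n_spikes number of spikes to generate (>= 2).
#' @param seed optional integer seed.
#' @export
fractal_train_config <- function(target_H = 0.8, mean_isi = 0.1,
                                 isi_dispersion = 1, n_spikes = 4096,
                                 seed = NULL) {
  stopifnot(target_H > 0, target_H < 1, mean_isi > 0, isi_dispersion >= 0,
            n_spikes >= 2)
  structure(list(target_H = target_H, mean_isi = mean_isi,
                 isi_dispersion = isi_dispersion,
                 n_spikes = as.integer(n_spikes), seed = seed),
            class = "fractal_train_config")
}

#' Fractal ISI spike train
#'
#' Generates a spike train whose ISI sequence carries tunable long-range
#' correlations: with `g` a unit-variance fGn of Hurst exponent `target_H`,
#' \deqn{ISI_i = \mu \exp(\sigma g_i - \sigma^2/2),}
#' so every ISI is positive and `E[ISI] = mu`.  Timestamps are the cumulative
#' sums; the record duration is set to the last timestamp.
#'
#' @param config a [fractal_train_config()], or `NULL` to build one from `...`.
#' @param ... passed to [fractal_train_config()] when `config` is `NULL`.
#' @inheritParams spike_train
#' @return a `spike_train`.
#' @examples
#' tr <- generate_fractal_isi_train(fractal_train_config(target_H = 0.7,
#'   n_spikes = 256, seed = 1))
#' @export
generate_fractal_isi_train <- function(config = NULL, ...,
                                       condition = "baseline",
                                       cell_type = "unspecified",
                                       unit_id = "fractal") {
  if (is.null(config)) config <- fractal_train_config(...)
  stopifnot(inherits(config, "fractal_train_config"))
  sig <- config$isi_dispersion
  isi <- if (sig == 0) {
    rep(config$mean_isi, config$n_spikes - 1L)
  } else {
    g <- generate_fgn(config$n_spikes - 1L, config$target_H, seed = config$seed)
    config$mean_isi * exp(sig * g - sig^2 / 2)
  }
  ts <- c(0, cumsum(isi))
  spike_train(ts, duration = ts[length(ts)], condition = condition,
              cell_type = cell_type, unit_id = unit_id)
}

#' Configuration for a sinusoidally entrained spike train
#'
#' Models a unit driven by periodic (default 50 Hz) sinusoidal stimulation
#' with stochastic cycle skipping: each stimulation cycle elicits at most one
#' spike, with marginal probability `per_cycle_probability`, and the
#' cycle-success process carries long-range correlations set by `failure_H`
#' (intermittent conduction block produces runs of skipped cycles, hence ISIs
#' at integer multiples of the cycle period).  Spikes sit at a preferred
#' phase within the cycle — by default three quarters through, the negative
#' peak of a sine starting at phase zero — plus Gaussian jitter.
#'
#' @param stim_frequency stimulation frequency in Hz (default 50; cycle
#'   period 20 ms).
#' @param per_cycle_probability probability p in \code{[0, 1]} that a cycle
#'   elicits a spike (coupling ratio); defaults near the interneuron value.
#' @param failure_H Hurst exponent in (0, 1) of the latent cycle-success
#'   process; 0.5 gives independent skipping.
#' @param phase_jitter_sd SD (seconds) of the spike-time jitter around the
#'   preferred phase.
#' @param preferred_phase_offset offset in seconds within the cycle; default
#'   `0.75 / stim_frequency`.
#' @param duration record length in seconds (default 60, a 1-min stimulation).
#' @param seed optional integer seed.
#' @export
entrainment_config <- function(stim_frequency = 50,
                               per_cycle_probability = 0.65,
                               failure_H = 0.8,
                               phase_jitter_sd = 0.001,
                               preferred_phase_offset = 0.75 / stim_frequency,
                               duration = 60, seed = NULL) {
  stopifnot(stim_frequency > 0,
            per_cycle_probability >= 0, per_cycle_probability <= 1,
            failure_H > 0, failure_H < 1,
            phase_jitter_sd >= 0,
            preferred_phase_offset >= 0,
            preferred_phase_offset < 1 / stim_frequency,
            duration > 0)
  structure(list(stim_frequency = stim_frequency,
                 per_cycle_probability = per_cycle_probability,
                 failure_H = failure_H,
                 phase_jitter_sd = phase_jitter_sd,
                 preferred_phase_offset = preferred_phase_offset,
                 duration = duration, seed = seed),
            class = "entrainment_config")
}

#' Sinusoidally entrained spike train with fractal cycle skipping
#'
#' For each stimulation cycle `k` (starting at `k / stim_frequency`), a spike
#' is emitted iff the latent fGn value for that cycle exceeds the
#' `(1 - p)` standard-normal quantile, which gives exact marginal success
#' probability `p` with long-range-correlated successes.  The spike is placed
#' at the cycle start plus the preferred phase offset plus Gaussian jitter.
#' The resulting ISI histogram peaks at integer multiples of the cycle period
#' (20, 40, 60 ms at 50 Hz).
#'
#' @param config an [entrainment_config()], or `NULL` to build one from `...`.
#' @param ... passed to [entrainment_config()] when `config` is `NULL`.
#' @param cell_type,unit_id labels for the resulting train.
#' @return a `spike_train` with `condition = "stimulation"`.
#' @examples
#' tr <- generate_entrained_train(entrainment_config(
#'   per_cycle_probability = 0.65, duration = 10, seed = 1))
#' @export
generate_entrained_train <- function(config = NULL, ...,
                                     cell_type = "unspecified",
                                     unit_id = "entrained") {
  if (is.null(config)) config <- entrainment_config(...)
  stopifnot(inherits(config, "entrainment_config"))
  p <- config$per_cycle_probability
  if (p == 0) stop("`per_cycle_probability` = 0 would produce an empty train")
  n_cycles <- floor(config$duration * config$stim_frequency)
  period <- 1 / config$stim_frequency
  ts <- with_seed(config$seed, {
    success <- if (p >= 1) {
      rep(TRUE, n_cycles)
    } else {
      generate_fgn(n_cycles, config$failure_H) >= stats::qnorm(1 - p)
    }
    t <- (which(success) - 1L) * period + config$preferred_phase_offset
    if (config$phase_jitter_sd > 0) {
      t <- t + stats::rnorm(length(t), 0, config$phase_jitter_sd)
    }
    t <- sort(t[t >= 0 & t <= config$duration])
    t[c(TRUE, diff(t) > 0)]
  })
  spike_train(ts, duration = config$duration, condition = "stimulation",
              cell_type = cell_type, unit_id = unit_id)
}

#' Baseline (pre-stimulation) spike train for a given cell type
#'
#' Emulates spontaneous hippocampal firing with weak long-range correlation.
#' Interneurons fire in a scattered fashion (default 9 spikes/s) and are
#' modelled as a fractal lognormal-ISI train.  Pyramidal cells fire sparsely
#' (default 2.5 spikes/s) in bursts: burst-onset events follow a fractal
#' train, and after each spike another intra-burst spike follows with
#' probability `burst_fraction` at a short lognormal ISI (mode near
#' `burst_isi`), so `burst_fraction` is approximately the fraction of ISIs
#' shorter than ~8 ms.
#'
#' @param cell_type `"pyramidal"` or `"interneuron"`.
#' @param rate target mean firing rate in spikes/s; defaults 2.5 (pyramidal)
#'   and 9 (interneuron).
#' @param duration record length in seconds.
#' @param correlation_H Hurst exponent of the driving fGn (weakly persistent
#'   default 0.55).
#' @param isi_dispersion lognormal log-scale spread of the slow ISI component.
#' @param burst_fraction probability that a spike is followed by another
#'   intra-burst spike (pyramidal only).
#' @param burst_isi median intra-burst ISI in seconds (pyramidal only).
#' @param burst_isi_spread lognormal log-scale SD of intra-burst ISIs.
#' @param seed optional integer seed.
#' @param unit_id identifier for the unit.
#' @return a `spike_train` with `condition = "baseline"`.
#' @export
generate_baseline_train <- function(cell_type = c("pyramidal", "interneuron"),
                                    rate = NULL, duration = 60,
                                    correlation_H = 0.55, isi_dispersion = 1,
                                    burst_fraction = 0.35, burst_isi = 0.005,
                                    burst_isi_spread = 0.3,
                                    seed = NULL, unit_id = cell_type) {
  cell_type <- match.arg(cell_type)
  if (is.null(rate)) rate <- if (cell_type == "pyramidal") 2.5 else 9
  stopifnot(rate > 0, duration > 0,
            burst_fraction >= 0, burst_fraction < 1, burst_isi > 0)
  ts <- with_seed(seed, {
    if (cell_type == "interneuron") {
      n <- max(16L, ceiling(rate * duration * 1.6))
      g <- generate_fgn(n, correlation_H)
      isi <- (1 / rate) * exp(isi_dispersion * g - isi_dispersion^2 / 2)
      t <- cumsum(isi)
      t[t <= duration]
    } else {
      # burst-onset events; mean spikes per burst = 1 / (1 - burst_fraction)
      event_rate <- rate * (1 - burst_fraction)
      n <- max(16L, ceiling(event_rate * duration * 1.6))
      g <- generate_fgn(n, correlation_H)
      gap <- (1 / event_rate) * exp(isi_dispersion * g - isi_dispersion^2 / 2)
      onsets <- cumsum(gap)
      onsets <- onsets[onsets <= duration]
      extra <- stats::rgeom(length(onsets), 1 - burst_fraction)
      sp <- unlist(lapply(seq_along(onsets), function(i) {
        k <- extra[i]
        if (k == 0L) return(onsets[i])
        onsets[i] + cumsum(c(0, exp(stats::rnorm(k, log(burst_isi),
                                                 burst_isi_spread))))
      }))
      sp <- sort(sp[sp <= duration])
      sp[c(TRUE, diff(sp) > 0)]
    }
  })
  spike_train(ts, duration = duration, condition = "baseline",
              cell_type = cell_type, unit_id = unit_id)
}

#' Shuffle surrogate of an ISI sequence
#'
#' Random permutation of the intervals: the ISI distribution (hence mean, SD,
#' CV) is preserved exactly while the temporal ordering — and with it any
#' long-range correlation — is destroyed.  The Hurst exponent of a shuffled
#' fractal sequence reverts to ~0.5 and the Fano scaling exponent of the
#' rebuilt train to ~0.
#'
#' @param isis an `isi_sequence` (or spike train / interval vector).
#' @param seed optional integer seed.
#' @return an `isi_sequence` with permuted intervals.
#' @export
shuffle_surrogate <- function(isis, seed = NULL) {
  iv <- as_intervals(isis)
  if (length(iv) < 2L) stop("need at least 2 intervals to shuffle")
  new_isi_sequence(with_seed(seed, sample(iv)))
}
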