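# spikefractal

Fractal analysis of neuronal spike trains in R.

Neurons rarely fire as memoryless point processes: inter-spike intervals
(ISIs) carry long-range correlations — clusters of short and long intervals
recurring across many time scales — and periodic afferent stimulation (e.g.
50 Hz sinusoidal drive of hippocampal afferents) reshapes that structure by
entraining spikes to the stimulus cycle while conduction fails
intermittently.  `spikefractal` is for electrophysiologists and
computational neuroscientists who want to quantify this structure in unit
recordings and to validate the whole pipeline against synthetic ground
truth.

It implements:

* **Fano factor curve** `F(T) = var(N_i(T)) / mean(N_i(T))` over counting
  windows `T` (default 0.1–10 s, log-spaced) and its **scaling exponent α**,
  the double-log slope over the scaling region (`F(T) ∝ T^α`; ~1 for
  Poisson firing, → 0 for periodic, `0 < α ≤ 1` for fractal firing).
* **Rescaled-range Hurst exponent** of the ISI sequence: per segment length
  `d`, `(R/S)_d = (1/M) Σ R_m/S_m` from the range of accumulated
  mean-deviations over adjacent segments; `H` is the double-log slope
  (`H = 0.5` independent, `> 0.5` persistent, `< 0.5` antipersistent).
* **Approximate Entropy** (classic ApEn, `m = 2`, `r = 0.15 × SD`,
  Chebyshev distance, self-matches included), **CV of ISIs**, ISI-range
  fractions (burst range 0–8 ms, entrainment peak 19–21 ms) and
  probability-normalised **ISI histograms** with dominant-peak detection.
* **Seeded generators**: homogeneous Poisson and (jittered) periodic
  controls; exact fractional Gaussian noise (Davies–Harte circulant
  embedding); fractal lognormal-ISI trains with a target Hurst exponent;
  50 Hz-entrained trains with long-range-correlated cycle skipping at exact
  marginal coupling probability; bursty pyramidal-like and scattered
  interneuron-like baseline trains; shuffle surrogates.
* A **cohort experiment driver** (`run_experiment()`): paired
  baseline-vs-stimulation design over a synthetic cohort (default 25
  pyramidal-like + 14 interneuron-like units), Shapiro–Wilk checks and
  paired t-tests per metric, CSV/JSON outputs, and a thin command-line
  front end (`inst/cli/spikefractal` with `simulate`, `analyze`,
  `experiment` subcommands).

## Worked example

```r
library(spikefractal)

base <- generate_baseline_train("interneuron", duration = 60, seed = 11)
stim <- generate_entrained_train(entrainment_config(
  per_cycle_probability = 0.65, failure_H = 0.8, duration = 60, seed = 12),
  cell_type = "interneuron")
base; stim
#> <spike_train> unit 'interneuron' (interneuron, baseline): 541 spikes in 60 s (9.02 spikes/s)
#> <spike_train> unit 'entrained' (interneuron, stimulation): 1529 spikes in 60 s (25.48 spikes/s)

isi_histogram(stim, bin_width_ms = 1)
#> <isi_histogram> 1528 intervals, 599 bins of 1 ms; dominant peak at 20 ms
isi_fraction(stim, 19, 21)
#> [1] 0.365

fano_curve(base); fano_curve(stim)
#> <fano_curve> 21 window sizes in [0.1, 10] s; 541 spikes
#>   alpha = 0.258 over [0.316, 10] s (R^2 = 0.851)
#> <fano_curve> 21 window sizes in [0.1, 10] s; 1529 spikes
#>   alpha = 0.667 over [0.316, 10] s (R^2 = 0.965)

hurst_exponent(to_isi(base)); hurst_exponent(to_isi(stim))
#> [1] 0.635
#> [1] 0.648

hurst_exponent(shuffle_surrogate(to_isi(stim), seed = 1))
#> [1] 0.586
```

Reading: the stimulated unit fires at ~25 spikes/s (coupling ratio ~0.5 of
the 50 Hz drive), its dominant ISI peak sits exactly at the 20 ms cycle with
36.5% of ISIs in 19–21 ms, and its Fano exponent (0.667) is far above the
baseline value (0.258) — entrainment with correlated cycle-skipping
*increases* long-range correlation.  Shuffling the stimulated ISI sequence
pulls `H` back toward the estimator's independence level, confirming the
correlation lives in the interval *ordering*, not the distribution.  (The
raw R/S estimator's i.i.d. null sits near 0.57 at these lengths, a
documented small-sample bias; see the methods vignette.)

The full paired cohort:

```r
res <- run_experiment(experiment_config(seed = 2024), alternative = "greater")
res$tests   # per (cell_type, metric): mean ± SD per condition, paired t, p
```

## Layout

* `R/` — generators, metrics, Fano, R/S, cohort driver
* `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracles for ApEn, R/S and window counting
* `vignettes/spikefractal-methods.Rmd` — models, assumptions, parameter
  defaults, numerical choices, limitations
* `inst/cli/spikefractal` — command-line front end
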