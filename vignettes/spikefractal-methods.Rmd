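---
title: "Quantifying long-range correlations in neuronal spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying long-range correlations in neuronal spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefractal)
```

## The problem

Cortical and hippocampal neurons do not fire as memoryless point processes.
Their inter-spike intervals (ISIs) often carry *long-range correlations*:
clusters of short and long intervals recur across many time scales, a
signature of fractal point processes.  Periodic afferent drive — for
example 50 Hz sinusoidal stimulation of the Schaffer collaterals while
recording downstream CA1 units — reshapes this structure: units lock to a
preferred phase of the stimulus but skip cycles intermittently, producing
ISIs at integer multiples of the 20 ms cycle and, when the skipping itself
is history-dependent, *stronger* long-range correlations than at rest.

`spikefractal` implements the two standard fractal indices for spike
trains, the supporting first-order statistics, and a family of generative
models that reproduce the statistical structure the estimators assume, so
that every estimator can be validated in closed loop against known ground
truth.

## Estimators

### Fano factor and scaling exponent

For a counting-window size $T$, the record $[0, D]$ is partitioned into
$\lfloor D/T \rfloor$ contiguous non-overlapping windows anchored at $t=0$
(the trailing remainder is discarded) and the Fano factor is

$$F(T) = \frac{\operatorname{var}(N_i(T))}{\operatorname{mean}(N_i(T))},$$

with $N_i(T)$ the spike count in window $i$ and the sample variance
($n-1$ denominator, as everywhere in this package).  For a Poisson process
$F(T) \approx 1$ at every $T$; for a periodic process $F(T) \to 0$; for a
fractal process $F(T) \propto T^{\alpha}$ over a scaling region, with
$0 < \alpha \le 1$ for this estimator.  `fano_curve()` evaluates $F$ on a
log-spaced grid (default 10 points/decade from 0.1 to 10 s) and
`fano_alpha()` fits $\alpha$ as the OLS slope of $\log_{10} F$ versus
$\log_{10} T$ over a fit range that defaults to $10^{-0.5}$–$10$ s, the
empirically observed onset of power-law scaling in 1-min unit recordings.
Both ranges are arguments, not constants.

Two numerical details matter here:

* **Window-count minimum.** Grid points with fewer than `min_windows = 4`
  complete windows are dropped; at $T = 10$ s a 60 s record retains only 6
  windows, which is the price of following the conventional 0.1–10 s range
  on 1-min records.
* **Log-domain debiasing.** With so few windows $F(T)$ is nearly unbiased
  but $\log F(T)$ is not: for near-Poisson counts the variance-over-mean
  from $n$ windows behaves like $\chi^2_{n-1}/(n-1)$, whose logarithm has
  expectation $\psi(\tfrac{n-1}{2}) - \ln\tfrac{n-1}{2} < 0$.  Left
  uncorrected this tilts the fitted slope of a *flat* curve to about
  $-0.08$ on 60 s records.  `fano_alpha(log_debias = TRUE)` (the default)
  subtracts this offset per grid point before fitting — the same digamma
  correction used in log-periodogram regression.  When every retained grid
  point has the same window count the correction is a constant shift, so
  exact power laws are recovered unchanged.

### Rescaled-range (R/S) Hurst exponent

The Hurst exponent is estimated on the ISI sequence.  For each segment
length $d$ on a log-spaced integer grid from 4 to $\lfloor N/3 \rfloor$
(about 15 points), the first $M d$ intervals ($M = \lfloor N/d \rfloor$;
the tail is discarded) form $M$ adjacent segments.  Within segment $m$,
with mean $E_m$ and sample SD $S_m$, the accumulated deviations
$X_{k,m} = \sum_{i \le k} (\mathrm{ISI}_{i,m} - E_m)$ give the range
$R_m = \max_k X_{k,m} - \min_k X_{k,m}$, and

$$(R/S)_d = \frac{1}{M} \sum_{m=1}^{M} R_m / S_m .$$

$H$ is the OLS slope of $\log_{10} (R/S)_d$ against $\log_{10} d$.
Independent ISIs give $H = 0.5$; $H > 0.5$ indicates persistence (long
intervals follow long ones), $H < 0.5$ antipersistence.  Segments with
$S_m = 0$ are excluded from the average (their count is reported in
`segments_used` / `segments_dropped`); a fully constant sequence is an
error rather than a number.

The classic R/S statistic is *biased upward for short series*: at the
smallest admissible segment length ($d = 4$) the expected $R/S$ of even an
i.i.d. sequence exceeds the asymptotic power law.  With the conventional
$d$-range used here the i.i.d. null of the raw estimator sits near 0.57
rather than 0.50 at $N = 4096$.  The package reports the raw estimator —
matching standard practice for this analysis — and the test suite
calibrates directional claims against the estimator's own null rather
than against 0.5; no Anis–Lloyd-style correction is applied.  Estimates
are never clipped into $[0, 1]$.

### Approximate Entropy, CV, and ISI-pattern statistics

`apen()` is classic ApEn (self-matches included, not sample entropy):
templates of length $m$ (default 2) compared under the Chebyshev distance
at tolerance $r$, with $\mathrm{ApEn} = \Phi^m(r) - \Phi^{m+1}(r)$.  The
tolerance is $r = 0.15 \times$ sample SD of the analysed sequence.  The
multiplier convention deserves a note: some reports state only "$r =
0.15$" without units; relative-to-SD is the convention of the ApEn
literature for physiological series and keeps the statistic
amplitude-invariant, so it is what this package implements.  ApEn is
computed on the ISI sequence, the only per-unit scalar series the pipeline
constructs.  For a constant sequence the relative tolerance degenerates to
$r = 0$; ApEn is then defined as 0 (all templates identical), not an
error.

`isi_cv()` is sample SD over mean.  `isi_fraction(lo, hi)` uses half-open
ranges $[lo, hi)$ in ms — the burst range "0–8 ms" is $[0, 8)$ and the
first entrainment peak "19–21 ms" is $[19, 21)$; the endpoint convention
is a package decision since prose ranges leave it open.  `isi_histogram()`
bins are also half-open, 1 ms wide by default, but *centred* on integer
multiples of the bin width (first bin $[-w/2, w/2)$): a unimodal peak at
exactly $n \times 20$ ms then falls inside a single bin instead of
splitting across an edge, which makes the reported dominant-peak location
stable across random seeds.

## Generators

All generators take an explicit `seed`, return bit-identical output for
identical (parameters, seed), and restore the caller's RNG state.

**Fractional Gaussian noise** (`generate_fgn()`) uses Davies–Harte
circulant embedding: the sampled sequence has *exactly* the fGn
autocovariance $\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} +
|k-1|^{2H})$, which the test suite checks against the closed form.  A
non-positive-definite embedding raises an error rather than truncating
eigenvalues silently (for fGn with $0 < H < 1$ the embedding is known to
be valid; the check guards the implementation, not the theory).

**Fractal ISI trains** (`generate_fractal_isi_train()`) apply a lognormal
link: $\mathrm{ISI}_i = \mu \exp(\sigma g_i - \sigma^2/2)$ with $g$ a
unit-variance fGn of Hurst exponent `target_H`.  Positivity is guaranteed
and $E[\mathrm{ISI}] = \mu$ exactly.  The monotone transform preserves the
Hurst exponent only approximately, which is why generator–estimator loop
closure is asserted at tolerance $\pm 0.1$, not exactness.

**Entrained trains** (`generate_entrained_train()`) model sinusoidal drive
with intermittent conduction block.  Each 20 ms cycle emits at most one
spike; cycle $k$ succeeds iff an fGn value exceeds the $(1-p)$
standard-normal quantile, giving *exact* marginal probability $p$ with
long-range-correlated successes controlled by `failure_H`.  The spike
sits at a preferred phase — default three quarters through the cycle, the
negative peak of a sine starting at phase 0 — plus Gaussian jitter
(default SD 1 ms).  Defaults for $p$ follow the coupling ratios of the
motivating preparation: 0.65 (interneuron-like, ~32.5 spikes/s at 50 Hz)
and 0.10 for pyramidal-like units.  Note that with `failure_H > 0.5` the
spike *count* is overdispersed relative to a binomial with the same $p$ —
that is the point of the model — so count-based sanity checks against the
binomial interval are only valid at `failure_H = 0.5`.

**Baseline trains** (`generate_baseline_train()`) emulate spontaneous
firing.  Interneuron-like units (default 9 spikes/s) are fractal
lognormal-ISI trains.  Pyramidal-like units (default 2.5 spikes/s) are
bursty: burst onsets follow a fractal train and each spike is followed by
another intra-burst spike with probability `burst_fraction` at a short
lognormal ISI (median 5 ms), so mean burst size is
$1/(1-\mathrm{burst\_fraction})$ and `burst_fraction` approximates the
fraction of ISIs below ~8 ms.  The default 0.35 reproduces the ~35%
short-ISI fraction typical of baseline pyramidal recordings; no claim of
mechanistic ground truth attaches to it.  Baseline long-range correlation
defaults to a weakly persistent `correlation_H = 0.55`.

**Shuffle surrogates** (`shuffle_surrogate()`) permute the ISI sequence:
the ISI distribution, mean, SD and CV are preserved exactly while temporal
order — and with it any long-range correlation — is destroyed.  Shuffled
fractal trains return $H$ to the estimator's i.i.d. null and $\alpha$
to ~0, the standard surrogate control for fractal structure.

## The cohort experiment

`run_experiment()` composes the above into the full paired design: for
each unit a baseline and a stimulation train are generated (per-unit seeds
derived deterministically from the master seed), all metrics computed
(`rate`, `cv`, `apen`, `frac_0_8ms`, `frac_19_21ms`, `alpha`, `H`), and
per (cell type, metric) a Shapiro–Wilk normality check per condition plus
a paired t-test on the per-unit differences.  Defaults are a 25 + 14
cohort (pyramidal-like + interneuron-like), 60 s per condition.  Raw
two-sided p-values are reported with no multiple-testing correction — the
analysis battery this mirrors reports per-metric paired tests only — and
`alternative = "greater"` is available for directional hypotheses.  Units
failing a metric (e.g. too few spikes for R/S) are excluded pairwise for
that metric and logged in `$failures`; the run fails only if fewer than 3
paired units remain.  An unpaired Welch t-test (`unpaired_comparison()`,
pooled-variance optional) covers between-cell-type contrasts.

Setting `stimulation_model = "baseline"` draws the "stimulation" trains
from the baseline generator with independent seeds, which makes the two
conditions identically distributed — the type-I calibration used by the
test suite (rejection rate at the 5% level stays near nominal).

## What the synthetic data does and does not show

The generators reproduce the *statistical* structure the estimators
assume: exact fGn autocovariance, exact marginal coupling probability,
ISI peaks at cycle multiples, tunable persistence.  They deliberately omit
biophysics and measurement artifacts of real recordings: no refractory
interaction between the burst process and the slow process beyond the
generative recipe, no rate nonstationarity within a record, no spike
sorting errors or missed spikes, no biophysical model of conduction block
(potassium accumulation, sodium-channel recovery), and spikes are point
events with no waveform.  Passing the loop-closure tests therefore
validates the estimators and the pipeline, not any claim about biological
recordings; conversely, real-data deviations from these idealisations
(especially nonstationarity, which both $F(T)$ and R/S conflate with
long-range correlation) remain the user's responsibility to assess.

## Problem sizes and tolerances used by the test suite

The suite validates estimators at the scale the analysis targets: 60 s
records, ISI sequences of $N = 4096$ for Hurst recovery (20 seeds per
condition; recovery tolerance $\pm 0.1$; i.i.d. control $\pm 0.08$),
20-seed ensembles for the Poisson Fano control (grand-mean tolerance
$\pm 0.1$), 5 correlation strengths × 20 seeds for the $\alpha \le 1$
ceiling, and a full 25 + 14-unit cohort for the directional paired
effects at $p < 0.05$.  Oracle-equivalence checks (brute-force ApEn,
loop-literal R/S, direct-membership window counts) run on ~100 random
small inputs each at tolerances $10^{-10}$–$10^{-12}$.  Exact claims
(periodic $F = 0$ at period multiples, surrogate multiset preservation,
determinism) are asserted exactly.
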