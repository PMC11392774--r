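Package: spikefractal
Title: Fractal Analysis of Neuronal Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify long-range correlations (fractal structure)
    in neuronal spike trains: the Fano-factor curve F(T) and its scaling
    exponent alpha, the rescaled-range (R/S) Hurst exponent of inter-spike
    intervals, Approximate Entropy, the coefficient of variation, and
    ISI-histogram pattern statistics.  Includes seeded generators for
    Poisson, periodic, fractal (fractional-Gaussian-noise driven) and
    sinusoidally entrained spike trains with long-range-correlated cycle
    skipping, plus a cohort-level experiment driver with paired
    baseline-versus-stimulation statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
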