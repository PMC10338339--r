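# pcqls — photon-counting quantum light spectroscopy

`pcqls` simulates and analyses **heralded single-photon fluorescence
experiments**: a pulsed spontaneous parametric down-conversion (SPDC)
source produces photon pairs; one photon of each pair (the *herald*) is
detected directly, while its partner excites a fluorescent sample — the
motivating system is the LH2 antenna complex of purple bacteria — whose
re-emitted photon is detected after spectral filtering. Every detection is
time-tagged, and all of the physics is extracted from coincidence counting
on the multi-channel time-tag streams.

The package is aimed at single-molecule / quantum-optics spectroscopists
who want to (a) model such an experiment end to end before building it,
(b) analyse time-tag data with well-tested counting statistics, or
(c) verify the statistical machinery behind published photon-counting
claims on synthetic data with known ground truth.

## What it computes

With pump repetition rate $R_r$, mean pair number per pulse
$n_p = R_p/R_r$, and lumped heralded-fluorescence channel efficiency
$e_{hf} = R_{hf}/R_h$:

* **Pair statistics** — single-mode thermal (squeezed-vacuum) pair number
  law $P(M) = n_p^M/(1+n_p)^{M+1}$ and the $M$-photon weights among
  heralded pulses $n_p^{M-1}/(1+n_p)^M$.
* **Conditional antibunching** — the gated three-detector estimator
  $g^{(2)}(0) = (N_H\,N_C)/(N_2\,N_3)$ with Poisson error propagation;
  values below 0.5 certify single-photon character. Closed-form reference
  line $g^{(2)}(0) = 2n_p/(1+n_p)$.
* **Counting statistics** — the distribution $P(N)$ of the number of
  heralds per heralded fluorescence detection, geometric
  $P(N) = e_{hf}(1-e_{hf})^{N-1}$ (with $P(0)=0$; double detections in one
  gate populate the $N=0$ bin), its exponential-tail limit
  $P(N)\propto e^{-N e_{hf}}$, and maximum-likelihood fits of $e_{hf}$.
* **Fluorescence lifetime** — herald–fluorescence cross-correlation
  histograms (default 128-ps bins) fitted with a single exponential
  reconvolved with the instrument response function (IRF), by Poisson
  maximum likelihood with profile-likelihood confidence intervals.
* **Monte Carlo simulation** — stochastic-trajectory model of the whole
  experiment (thermal pairs, lossy click detectors, exponential emission,
  Gaussian jitter, dark counts, dead time, 50:50 splitter mode) emitting
  realistic `tag_stream` objects for all of the above.

## Worked example

```r
library(pcqls)

cfg <- experiment_config(duration_s = 0.2, p_detect_fluor = 0.05,
                         splitter = TRUE, seed = 42)
stream <- simulate_stream(cfg)
measure_rates(stream, gate_ps = cfg$gate_fluor)

hist <- crosscorrelate(stream, stream, bin_ps = 128, window_ps = 6600)
fit_lifetime(hist, irf_gaussian(0, sqrt(2) * cfg$irf_sigma))

conditional_g2(gated_counts(stream, gate_ps = 10000))
fit_geometric(herald_count_distribution(stream, gate_ps = 10000))
```

prints (abridged):

```
<tag_stream: 228583 tags on channels {1,2,3}>
R_h = 9.7e+05 /s, R_hf = 4.89e+04 /s, e_hf = 0.05044
<lifetime_fit: tau0 = 1213.1 ps, 95% CI [1185.7, 1241.4] ps>
conditional g2(0) = 0.122 +/- 0.031   (closed-form line: 0.0876)
geometric fit: e_hf = 0.05037 +/- 0.0005
```

Reading the numbers: the herald detector clicks at 9.7×10⁵ counts/s (the
calibrated operating point); the lifetime fit recovers the generator's
1200-ps decay within its confidence interval; the heralded g²(0) of 0.12
is far below the 0.5 single-photon threshold (the gap above the
closed-form line is the photon-number weighting of lossy heralding — see
the methods vignette); and the heralds-per-fluorescence distribution is
geometric with success probability equal to the channel efficiency that
was simulated (0.05).

Evaluating the estimator on the canonical published counts of a 5-h run:

```r
conditional_g2(list(N_H = 17773649622, N_C = 8,
                    N_2 = 819108, N_3 = 849299))
#> g2 = 0.2044, sd = 0.0723
```

A command-line interface wraps the same operations
(`inst/cli/pcqls.R simulate | analyze xcorr|g2|pn | fit |
reproduce fig1|fig2|fig3`); streams are stored as self-describing
tab-separated text files.

## Layout

* `R/` — data model & I/O (`timetags`), closed-form models (`models`),
  Monte Carlo engine (`simulator`), coincidence analyses (`correlator`),
  lifetime fitting (`lifetime`), orchestration & CLI (`pipeline`, `cli`).
* `tests/testthat/` — unit, property-based (brute-force oracle
  equivalence) and acceptance tests.
* `vignettes/pcqls-methods.Rmd` — the model, its assumptions, numerical
  choices and limitations.
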