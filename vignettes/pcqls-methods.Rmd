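---
title: "Models and methods behind pcqls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pcqls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcqls)
```

# The experiment being modelled

A femtosecond-pumped nonlinear crystal produces photon pairs by
spontaneous parametric down-conversion at repetition rate $R_r$ (default
75.7 MHz, period 13.2 ns). One photon of each pair is sent to a herald
detector (D1); its partner excites a fluorescent sample whose emission —
for the motivating system, the B850 band of the LH2 antenna complex,
lifetime $\tau_0 \approx 1.2$ ns — is filtered and detected on D2 (or
split 50:50 onto D2/D3 for antibunching measurements). A monitor channel
(D0) can view the residual transmitted excitation light. Every detection
is time-tagged; all inference is coincidence counting on the tag streams.

Three headline analyses are supported:

1. the herald–fluorescence cross-correlation, whose positive-delay flank
   is the fluorescence decay convolved with the instrument response;
2. the gated three-detector conditional $g^{(2)}(0) =
   (N_H N_C)/(N_2 N_3)$, which certifies single-photon operation when
   below 0.5;
3. the distribution $P(N)$ of the number of heralds elapsed per heralded
   fluorescence detection, geometric with success probability $e_{hf}$
   under single-photon operation.

# Statistical model

**Pair number.** Per pulse the pair number $M$ is single-mode thermal,
$P(M) = n_p^M/(1+n_p)^{M+1}$, the photon-number law of one mode of a
two-mode squeezed vacuum. Conditioned on $M \ge 1$ the weights become
$n_p^{M-1}/(1+n_p)^M$ — the multi-photon contamination of heralded
pulses. A multimode source would instead approach Poisson statistics; we
deliberately adopt the single-mode law because it reproduces those
heralded weights exactly, and we quantify the consequences below.

**Detection.** Every detector is a non-number-resolving click detector:
per pulse and channel at most one tag survives (the earliest arrival).
The herald arm detects each of the $M$ herald-side photons independently
with probability $\eta_h$, so the click probability is
$1-(1-\eta_h)^M$. Each signal photon independently yields a detected
fluorescence with the lumped probability `p_detect_fluor`, which absorbs
sample transmission, absorption, energy transfer, emission quantum yield,
collection, filtering and detector efficiency — only this product is
observable, as the channel efficiency $e_{hf} = R_{hf}/R_h$. Detected
emissions are delayed by $\mathrm{Exp}(\tau_0)$ and every tag carries
independent Gaussian timing jitter of s.d. `irf_sigma`. Homogeneous
Poisson dark counts and a non-paralysable dead time are available and
default to off/zero, matching an analysis that never corrects for either.

**Calibration of $\eta_h$.** The click rate of the herald detector under
thermal pairs is $R_h = R_r\, n_p \eta_h/(1+n_p\eta_h)$. The default
$\eta_h = 0.2843$ inverts this relation so the simulated click rate
equals the canonical operating point $R_h = 9.73\times 10^5$ counts/s at
$n_p = 0.0458$. The naive ratio $R_h/R_p = 0.2804$ would undershoot the
click rate by 1.3% because it ignores click saturation of multi-pair
pulses; we prioritise fidelity to the observable rate.

# The conditional g²(0) and its closed form

The closed-form reference $g^{(2)}(0) = 2 n_p/(1+n_p)$ is exact for a
herald that fires iff the pulse contained at least one pair
($\eta_h = 1$). A *lossy* Bernoulli herald prefers pulses with larger
$M$ (click probability $1-(1-\eta_h)^M$ grows with $M$), and under
single-mode thermal statistics the exact expectation of the three-detector
estimator sits above the closed form — at $n_p = 0.0458,\ \eta_h = 0.284$
the click-model value is $\approx 0.143$ versus $0.088$, essentially
independent of the fluorescence-channel efficiency. The two are
experimentally indistinguishable until several hundred gated coincidences
have been accumulated; the canonical 5-h run collected $N_C = 8$. The
acceptance test therefore checks theory–simulation agreement at that
coincidence scale (durations derived *a priori* from the closed-form
click-model expectation, targeting $E[N_C] \approx 10$ per rate), where
the 3-s.d. criterion is the statistically meaningful statement. Running
the same comparison at vastly larger $N_C$ would resolve the
photon-number-weighting correction and the closed form would fail — a
model limitation, not a simulation artifact. Both detector orderings are
symmetric in the estimator, and for independent Poissonian channels it
converges to 1 (tested).

**Gate-edge losses.** Gates open at the herald tag (offset configurable,
default 0, as no electronic delay is specified). Because both tags
jitter, the delay axis carries jitter $\sqrt 2\,\sigma$, and a few per
cent of the IRF-broadened rising edge falls *before* the gate opens;
this loss is part of the lumped $e_{hf}$, exactly as all other losses.

# P(N): counting heralds between fluorescence detections

Heralds are scanned in time order; when a herald's gate (default 10 ns,
truncated at the next herald, each tag attributed to its most recent
herald) contains at least one fluorescence tag, the number of heralds
since the previous recorded event (inclusive) is recorded and the counter
reset. If one gate contains two detections, the extra detection enters
the $N = 0$ bin — these are the same events counted as $N_C$ in the g²
measurement, and the package cross-checks the two paths. Diagnostics
split doubles into cross-detector and same-detector multiples (the latter
are impossible under click detection and would flag an import problem).

The geometric fit uses the closed-form MLE $\hat e_{hf} = 1/\bar N$ over
$N \ge 1$ with the observed-information standard error
$\sqrt{\hat e^2(1-\hat e)/n}$; the $N=0$ bin is excluded because the
model assigns it zero probability. The exponential-tail slope is fitted
by a Poisson log-linear GLM rather than least squares on log counts,
whose sparse-tail bias would otherwise exceed the slope's standard error
at realistic event totals.

# Lifetime fitting

The model for binned delay counts is
$\mu_i = A\,[\mathrm{IRF} \ast f_{\tau_0}](\mathrm{bin}_i - t_0) + B$
with $f_{\tau}$ the normalised exponential density, fitted by Poisson
maximum likelihood — the low-count tail of a decay histogram strongly
violates least-squares assumptions. Two IRF routes are implemented and
cross-validated against each other: a parametric Gaussian (ex-Gaussian
per-bin CDF differences, evaluated in log space so the exponential factor
cannot overflow against the underflowing normal tail) and an empirical
IRF (finite mixture over the area-normalised herald–residue
cross-correlation histogram, exact per-bin exponential mass). A delta IRF
reduces the model to a pure exponential; this limit is tested to 0.1%.

Initialisation is deterministic: $\tau$ from the weighted log-linear
slope of the post-peak tail, $t_0$ from the IRF centre, background from
the pre-rise median. The 95% interval on $\tau_0$ is a profile
likelihood: the profile is walked outward with warm-started nuisance
optimisation (continuation), then the deviance crossing
$\chi^2_{1,0.95}$ is bracketed and refined by root finding. Empirical
coverage at 2.5×10⁴-event histograms is ≈95% over 200 synthetic
repetitions (acceptance criterion 4).

**IRF estimation.** The herald–residue cross-correlation carries the
combined jitter of both detectors; the `irf` object reports both the
delay-axis width `sigma` (what reconvolution needs) and
`sigma_per_detector = sigma/sqrt(2)` (what a spec sheet quotes). The
moment-based Gaussian summary subtracts a flat background estimated from
the outer bins.

# Synthetic data: what it emulates, and what not

The generator's stated world uses the canonical parameters: $R_r = 75.7$
MHz; $n_p \in \{0.0458, 0.0214, 0.0103\}$ (a fourfold incident-rate
range); $e_{hf} = 1.244\times10^{-4}$ as the default lumped efficiency;
$\tau_0 = 1200$ ps; gates of 10 ns (fluorescence) and 6 ns (incident).
The per-detector jitter default of 150 ps (FWHM ≈ 353 ps) is our choice
of a typical single-photon-counting-module response, since only a
graphical IRF is available; lifetime recovery is validated across
$\sigma \in [50, 300]$ ps. Excitation saturation and annihilation are
omitted: with the repetition period ≫ lifetime and single-photon-level
flux there is at most one excitation in the ensemble at a time by
construction, which is the very regime the method targets.

*Desk scaling.* A literal 200-s stream at these rates holds ~2×10⁸
herald tags; tests and pipelines instead simulate runs whose *event
totals* match (e.g. ~2.4×10⁴ heralded-fluorescence events, the 200-s
equivalent) by boosting the lumped efficiency and shortening the
duration. Heralded g², the shape of $P(N)$ and the delay distribution are
first-order independent of the lumped efficiency, so the boost rescales
statistics without changing the physics; residual second-order effects
(same-channel double detections clipped by the click rule, at most a few
per mil of tags at the boosted efficiencies used) are kept below the
statistical resolution of the tests. A green test therefore establishes
correctness of the counting machinery and estimator calibration at
matched statistical power — not agreement with any particular laboratory
dataset, whose raw streams are not available.

Implementation note: only pulses containing at least one pair are ever
materialised (exact geometric inter-occurrence gaps; $M\,|\,M\ge 1$ by
memorylessness), so cost scales with occupied pulses, about
$n_p/(1+n_p) \times R_r \times$ duration. With a fixed seed streams are
bit-reproducible; repeated experiments derive independent sub-seeds.

# Numerical choices

* Timestamps are integer picoseconds held in doubles; validation rejects
  acquisitions beyond $2^{53}$ ps (~2.5 h), keeping all arithmetic exact
  without an int64 dependency. The 1-ps base deliberately over-resolves
  any sub-nanosecond tagger.
* Histogram bins are half-open $[lo, hi)$ with floor binning aligned to
  zero; pair counts are conserved exactly and checked against an
  all-pairs brute-force oracle on random instances.
* Infinite sums over photon number truncate when terms fall below
  $10^{-15}$ of the running total (identity tests assert $<10^{-12}$
  residuals).
* Ties at identical timestamps order by ascending channel, making stream
  round-trips deterministic; files are tab-separated text with a
  `# key=value` header that `read_stream()` inverts bit-exactly.
* `conditional_g2` works in doubles (count products overflow 32-bit
  integers), and substitutes the ±1-coincidence bound for the error when
  $N_C = 0$, flagged.

# Known limitations

* Single-mode thermal pair statistics are an idealisation; real
  femtosecond SPDC sources are partially multimode and sit between the
  thermal and Poisson limits, which matters only for the second-order
  correction to the g² closed form discussed above.
* No background/accidental subtraction is applied anywhere — the
  analyses report raw conditional counts, and dark counts default to
  zero.
* The lifetime model is strictly single-exponential; multi-exponential
  or stretched decays are out of scope.
* Vendor time-tagger binary formats are not parsed; any (channel, ps)
  table can be imported through the text format instead.
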