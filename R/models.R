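#' Pair-number statistics of a pulsed down-conversion source
#'
#' The photon-pair state produced by pulsed spontaneous parametric
#' down-conversion in a single Schmidt mode is a two-mode squeezed vacuum,
#' whose pair-number distribution per pump pulse is thermal (geometric on
#' M = 0, 1, 2, ...) with mean `n_p`:
#' \deqn{P(M) = n_p^M / (1 + n_p)^{M+1}.}
#'
#' @param n_p mean photon-pair number generated per pump pulse (= R_p / R_r).
#' @param M non-negative integer number of pairs (vectorized).
#' @return probability of generating exactly `M` pairs in one pulse.
#' @examples
#' pair_number_pmf(0.0458, 0:3)
#' @export
pair_number_pmf <- function(n_p, M) {
  if (any(n_p < 0)) stop("n_p must be non-negative")
  if (any(M != floor(M)) || any(M < 0)) stop("M must be a non-negative integer")
  # thermal pmf == geometric counting M failures with success prob 1/(1+n_p)
  stats::dgeom(M, prob = 1 / (1 + n_p))
}

#' Weight of the M-photon component among heralded pulses
#'
#' Conditioned on the pulse containing at least one pair (the situation a
#' herald detection selects, in the low-loss-independent limit), the weight
#' of the M-photon component of the signal field is
#' \deqn{w(M) = n_p^{M-1} / (1 + n_p)^{M}, \quad M = 1, 2, 3, \ldots}
#' which sums to 1 over M >= 1. The single-photon weight w(1) = 1/(1+n_p)
#' approaches 1 as `n_p` goes to 0.
#'
#' @param n_p mean pairs per pulse.
#' @param M integer photon number, `M >= 1` (vectorized).
#' @return probability weight of the M-photon component.
#' @examples
#' multiphoton_weight(0.0458, 1:3)
#' @export
multiphoton_weight <- function(n_p, M) {
  if (any(n_p < 0)) stop("n_p must be non-negative")
  if (any(M != floor(M)) || any(M < 1)) stop("M must be an integer >= 1")
  n_p^(M - 1) / (1 + n_p)^M
}

#' Theoretical heralded second-order coherence at zero delay
#'
#' Simple-model estimate of the conditional g2(0) measured by a
#' three-detector (herald + 50:50 splitter) arrangement on a thermal pair
#' source:
#' \deqn{g^{(2)}(0) = 2 n_p / (1 + n_p).}
#' It vanishes for an ideal heralded single photon and increases
#' monotonically with the pair rate, staying below 2.
#'
#' @param n_p mean pairs per pulse (vectorized).
#' @return the conditional g2(0) estimate.
#' @examples
#' heralded_g2_theory(c(0.0458, 0.0214, 0.0103))
#' @export
heralded_g2_theory <- function(n_p) {
  if (any(n_p < 0)) stop("n_p must be non-negative")
  2 * n_p / (1 + n_p)
}

#' Geometric distribution of heralds per heralded fluorescence detection
#'
#' Under single-photon operation every herald is an independent Bernoulli
#' trial with success probability `e_hf` (the overall heralded fluorescence
#' channel efficiency), so the number N of heralds elapsed per heralded
#' fluorescent detection is geometric:
#' \deqn{P(N) = e_{hf} (1 - e_{hf})^{N-1}, \quad N = 1, 2, 3, \ldots}
#' \deqn{P(N = 0) = 0.}
#' Its mode over N >= 1 is at N = 1 and its mean is 1/e_hf.
#'
#' @param e_hf heralded fluorescence channel efficiency, in (0, 1].
#' @param N non-negative integer herald count (vectorized).
#' @return probability.
#' @examples
#' geometric_pn(1.244e-4, 0:3)
#' @export
geometric_pn <- function(e_hf, N) {
  if (length(e_hf) != 1L || e_hf <= 0 || e_hf > 1)
    stop("e_hf must be a single value in (0, 1]")
  if (any(N != floor(N)) || any(N < 0)) stop("N must be a non-negative integer")
  p <- numeric(length(N))
  pos <- N >= 1
  p[pos] <- e_hf * (1 - e_hf)^(N[pos] - 1)
  p
}

#' Exponential-tail approximation of the herald-count distribution
#'
#' For very small efficiencies (e_hf << 1) the geometric distribution
#' reduces to a single-exponential decay, P(N) proportional to
#' exp(-N e_hf). This evaluates the matched form
#' `e_hf * exp(-(N - 1) * e_hf)`, which agrees with [geometric_pn()] to
#' relative order `(N-1) * e_hf^2 / 2`. A warning is issued outside the
#' stated validity regime (`e_hf > 0.01`), where the approximation visibly
#' disagrees with the exact geometric law.
#'
#' @param e_hf channel efficiency, `0 < e_hf <= 1` (small for validity).
#' @param N non-negative integer herald count (vectorized).
#' @return approximate probability (0 at N = 0).
#' @export
exp_tail_approx <- function(e_hf, N) {
  if (length(e_hf) != 1L || e_hf <= 0 || e_hf > 1)
    stop("e_hf must be a single value in (0, 1]")
  if (e_hf > 0.01)
    warning("exp_tail_approx is only valid for e_hf << 1 (got ", e_hf, ")")
  if (any(N != floor(N)) || any(N < 0)) stop("N must be a non-negative integer")
  p <- numeric(length(N))
  pos <- N >= 1
  p[pos] <- e_hf * exp(-(N[pos] - 1) * e_hf)
  p
}

#' Source statistics from printed rates
#'
#' Derives the mean pair number per pulse from the pair production rate and
#' the pump repetition rate, n_p = R_p / R_r, together with the repetition
#' period and the average interval between successive pairs.
#'
#' @param R_p pair production rate (pairs per second).
#' @param R_r pump repetition rate (Hz).
#' @return list with `n_p`, `R_p`, `R_r`, `rep_period_ns` (1/R_r in ns) and
#'   `mean_pair_interval_ns` (1/R_p in ns).
#' @examples
#' source_stats(R_p = 3.47e6, R_r = 75.7e6)
#' @export
source_stats <- function(R_p, R_r) {
  stopifnot(R_p >= 0, R_r > 0)
  list(n_p = R_p / R_r, R_p = R_p, R_r = R_r,
       rep_period_ns = 1e9 / R_r,
       mean_pair_interval_ns = if (R_p > 0) 1e9 / R_p else Inf)
}

#' Heralded fluorescence channel efficiency from rates
#'
#' e_hf = R_hf / R_h: the probability that a herald detection is accompanied
#' by a detected fluorescence photon, lumping every loss from the pair
#' source through the sample to the fluorescence detector.
#'
#' @param R_hf heralded fluorescence rate (counts per second).
#' @param R_h herald rate (counts per second).
#' @return list with `e_hf`, `R_hf`, `R_h`.
#' @examples
#' channel_efficiency(R_hf = 121, R_h = 9.73e5)
#' @export
channel_efficiency <- function(R_hf, R_h) {
  stopifnot(R_hf >= 0, R_h > 0)
  e <- R_hf / R_h
  if (e > 1) stop("R_hf cannot exceed R_h")
  list(e_hf = e, R_hf = R_hf, R_h = R_h)
}

#' Maximum-likelihood geometric fit of a herald-count distribution
#'
#' Fits the geometric law of [geometric_pn()] to an empirical
#' heralds-per-fluorescence distribution by maximum likelihood. For the
#' geometric distribution on N >= 1 the MLE is the reciprocal of the sample
#' mean, and the standard error follows from the observed Fisher
#' information: \eqn{se = \sqrt{\hat e^2 (1 - \hat e) / n}}. The N = 0 bin
#' (double-detection events, which the geometric law assigns zero
#' probability) is excluded from the likelihood.
#'
#' @param dist a [herald_count_distribution()] result, or any list with
#'   integer vectors `N` and `counts`.
#' @return list with `e_hf` (the estimate), `se`, `n_events` (events used,
#'   N >= 1 only) and `log_lik`.
#' @export
fit_geometric <- function(dist) {
  N <- dist$N
  counts <- dist$counts
  stopifnot(length(N) == length(counts), all(counts >= 0))
  keep <- N >= 1 & counts > 0
  n <- sum(counts[keep])
  if (n < 2) stop("fit_geometric needs at least 2 events with N >= 1")
  mean_N <- sum(as.numeric(N[keep]) * counts[keep]) / n
  e_hat <- 1 / mean_N
  se <- sqrt(e_hat^2 * (1 - e_hat) / n)
  ll <- sum(counts[keep] * log(geometric_pn(e_hat, N[keep])))
  list(e_hf = e_hat, se = se, n_events = n, log_lik = ll)
}
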