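#' Parametric Gaussian instrument response function
#'
#' The IRF on the herald-fluorescence *delay axis*. Note that when both the
#' herald and the fluorescence tag carry independent Gaussian jitter of
#' s.d. `sigma_det`, the delay-axis IRF is Gaussian with
#' `sigma = sqrt(2) * sigma_det`.
#'
#' @param t0 IRF centre on the delay axis (ps).
#' @param sigma Gaussian s.d. on the delay axis (ps); may be 0 (delta IRF).
#' @return object of class `irf`, type `"gaussian"`.
#' @export
irf_gaussian <- function(t0 = 0, sigma = 0) {
  stopifnot(sigma >= 0)
  structure(list(type = "gaussian", t0 = t0, sigma = sigma,
                 sigma_per_detector = sigma / sqrt(2)),
            class = "irf")
}

#' Empirical IRF from a delay histogram
#'
#' Wraps an area-normalized cross-correlation histogram as an empirical
#' IRF for reconvolution fitting.
#'
#' @param hist a [delay_histogram()] of the herald-residue
#'   cross-correlation.
#' @return object of class `irf`, type `"empirical"`, carrying the
#'   normalized histogram plus moment-based `t0` and `sigma`.
#' @export
irf_empirical <- function(hist) {
  stopifnot(inherits(hist, "delay_histogram"))
  if (sum(hist$counts) == 0) stop("empty IRF histogram")
  cen <- bin_centers(hist)
  p <- hist$counts / sum(hist$counts)
  t0 <- sum(cen * p)
  sigma <- sqrt(sum((cen - t0)^2 * p))
  structure(list(type = "empirical",
                 hist = normalize_histogram(hist, "area"),
                 mass = p, centers = cen,
                 t0 = t0, sigma = sigma,
                 sigma_per_detector = sigma / sqrt(2)),
            class = "irf")
}

#' @export
print.irf <- function(x, ...) {
  cat(sprintf("<irf: %s, t0 = %.1f ps, sigma = %.1f ps (%.1f ps per detector)>\n",
              x$type, x$t0, x$sigma, x$sigma_per_detector))
  invisible(x)
}

#' Estimate the instrument response from the incident-residue channel
#'
#' Cross-correlates heralds with the incident-residue monitor tags; the
#' resulting delay histogram, which carries no fluorescence delay, is the
#' empirical delay-axis IRF. A Gaussian summary (background-corrected
#' moment fit with standard errors) is attached for parametric use; its
#' `sigma_per_detector` field divides out the sqrt(2) combination of the
#' two detectors' independent jitters.
#'
#' @param heralds sorted herald times (ps) or a [tag_stream()].
#' @param residue_tags sorted residue-monitor times (ps), or a
#'   [tag_stream()] (channel 0 is used).
#' @param bin_ps histogram bin width (ps).
#' @param window_ps maximum |delay| (ps); keep below half the pulse period
#'   to exclude neighbouring-pulse correlations.
#' @return an `irf` object (type `"empirical"`) with fields `se_t0`,
#'   `se_sigma` and `n` added.
#' @export
estimate_irf <- function(heralds, residue_tags, bin_ps = 128,
                         window_ps = 3200) {
  if (inherits(residue_tags, "tag_stream"))
    residue_tags <- channel_times(residue_tags, 0L)
  if (length(residue_tags) == 0L) stop("empty residue channel")
  h <- crosscorrelate(heralds, residue_tags, bin_ps = bin_ps,
                      window_ps = window_ps)
  if (sum(h$counts) == 0) stop("no herald-residue coincidences in window")
  # flat accidental background estimated from the outer quarter of bins
  nb <- length(h$counts)
  outer_idx <- c(seq_len(ceiling(nb / 8)), seq(nb - ceiling(nb / 8) + 1, nb))
  bg <- stats::median(h$counts[outer_idx])
  cnt <- pmax(h$counts - bg, 0)
  if (sum(cnt) == 0) stop("residue correlation indistinguishable from background")
  irf <- irf_empirical(delay_histogram(h$bin_edges, h$counts))
  cen <- bin_centers(h)
  p <- cnt / sum(cnt)
  irf$t0 <- sum(cen * p)
  irf$sigma <- sqrt(sum((cen - irf$t0)^2 * p))
  irf$sigma_per_detector <- irf$sigma / sqrt(2)
  n <- sum(cnt)
  irf$n <- n
  irf$se_t0 <- irf$sigma / sqrt(n)
  irf$se_sigma <- irf$sigma / sqrt(2 * n)
  irf
}

# per-bin expected fraction of an IRF-convolved normalized exponential
# decay: edges in ps, decay time tau, shift t0
exp_conv_mass <- function(edges, tau, t0, irf) {
  if (irf$type == "gaussian") {
    sig <- irf$sigma
    mu <- t0 + irf$t0
    if (sig < 1e-9) {
      cdf <- stats::pexp(pmax(edges - mu, 0), rate = 1 / tau)
    } else {
      z <- (edges - mu) / sig
      # ex-Gaussian CDF, evaluated in log space to avoid overflow of the
      # exp factor against the underflowing normal tail
      cdf <- stats::pnorm(z) -
        exp(sig^2 / (2 * tau^2) - (edges - mu) / tau +
              stats::pnorm(z - sig / tau, log.p = TRUE))
      cdf[!is.finite(cdf)] <- 0
      cdf <- pmin(pmax(cdf, 0), 1)
    }
    return(diff(cdf))
  }
  # empirical IRF: finite mixture over IRF bins, exact per-bin exponential mass
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  m <- numeric(length(lo))
  for (j in seq_along(irf$mass)) {
    pj <- irf$mass[j]
    if (pj == 0) next
    sh <- irf$centers[j] + t0
    m <- m + pj * (stats::pexp(pmax(hi - sh, 0), 1 / tau) -
                     stats::pexp(pmax(lo - sh, 0), 1 / tau))
  }
  m
}

# Poisson negative log-likelihood of the reconvolution model
# par = (log tau, t0, log A, log B)
.lifetime_nll <- function(par, counts, edges, irf) {
  tau <- exp(par[1L])
  mu <- exp(par[3L]) * exp_conv_mass(edges, tau, par[2L], irf) +
    exp(par[4L]) + 1e-12
  sum(mu - counts * log(mu))
}

#' Fit a single-exponential fluorescence decay with IRF reconvolution
#'
#' Maximum-likelihood fit of the model
#' `counts_i ~ Poisson( A * (IRF (*) Exp(tau0))(bin_i - t0) + B )`
#' to a herald-fluorescence delay histogram — the standard reconvolution
#' fit of time-correlated single-photon-counting data, using the Poisson
#' likelihood appropriate for low-count tails rather than least squares.
#' The 95% confidence interval on `tau0` is obtained by profile
#' likelihood. Starting values are deterministic: `tau0` from the
#' log-linear slope of the post-peak tail, `t0` from the IRF centre.
#'
#' @param hist a [delay_histogram()] of raw counts (normalization
#'   `"none"`).
#' @param irf an `irf` object ([irf_gaussian()], [irf_empirical()] or
#'   [estimate_irf()] output) on the same delay axis.
#' @param conf confidence level for the interval (default 0.95).
#' @return object of class `lifetime_fit`: list with `tau0` (ps), `ci95`
#'   (ps, length 2), `amplitude`, `background` (counts per bin), `t0`
#'   (ps), `deviance`, `reduced_deviance`, `iterations`, `converged`.
#' @export
fit_lifetime <- function(hist, irf, conf = 0.95) {
  stopifnot(inherits(hist, "delay_histogram"), inherits(irf, "irf"))
  if (!identical(hist$normalization, "none"))
    stop("fit_lifetime needs raw counts (normalization 'none')")
  counts <- hist$counts
  edges <- hist$bin_edges
  w <- diff(edges[1:2])
  if (sum(counts > 0) < 10)
    stop("insufficient data: need >= 10 populated bins")
  cen <- bin_centers(hist)
  # --- deterministic initialization ---
  peak <- which.max(counts)
  tail_idx <- which(cen > cen[peak] + 2 * max(irf$sigma, w) & counts > 0)
  if (length(tail_idx) >= 3) {
    sl <- stats::lm.wfit(cbind(1, cen[tail_idx]), log(counts[tail_idx]),
                         w = counts[tail_idx])$coefficients[2L]
    tau_init <- if (is.finite(sl) && sl < 0) -1 / sl else w * 10
  } else tau_init <- w * 10
  tau_init <- min(max(tau_init, w / 4), diff(range(edges)))
  span <- max(cen) - cen[peak]
  if (span < 2 * tau_init)
    stop(sprintf(paste0("insufficient span: histogram covers %.0f ps past the",
                        " peak, need >= 2 lifetimes (%.0f ps)"), span,
                 2 * tau_init))
  t0_init <- 0
  bg_idx <- which(cen < cen[peak] - 4 * max(irf$sigma, w))
  bg_init <- max(if (length(bg_idx) >= 3) stats::median(counts[bg_idx]) else 0,
                 1e-8)
  A_init <- max(sum(counts) - bg_init * length(counts), 1)
  par0 <- c(log(tau_init), t0_init, log(A_init), log(bg_init))
  fit <- stats::optim(par0, .lifetime_nll, counts = counts, edges = edges,
                      irf = irf, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  fit <- stats::optim(fit$par, .lifetime_nll, counts = counts, edges = edges,
                      irf = irf, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("lifetime fit did not converge (optim code ", fit$convergence,
         ", ", fit$counts[1L], " evaluations)")
  nll_hat <- fit$value
  tau_hat <- exp(fit$par[1L])
  # --- profile-likelihood CI on tau0 ---
  crit <- stats::qchisq(conf, df = 1) / 2
  bound <- function(direction) {
    # continuation walk: warm-start the nuisance optimum from the previous
    # profile point so the inner optimizer converges reliably
    cache <- fit$par[-1L]
    prof <- function(log_tau) {
      opt <- stats::optim(cache,
                          function(q) .lifetime_nll(c(log_tau, q), counts,
                                                    edges, irf),
                          method = "Nelder-Mead",
                          control = list(maxit = 1500, reltol = 1e-11))
      cache <<- opt$par
      opt$value
    }
    step <- 0.02 * direction
    lo <- fit$par[1L]
    hi <- lo + step
    repeat {
      if (prof(hi) - nll_hat > crit) break
      lo <- hi
      hi <- hi + step
      if (abs(hi - fit$par[1L]) > 3) return(exp(fit$par[1L] + direction * 3))
    }
    r <- stats::uniroot(function(lt) prof(lt) - nll_hat - crit,
                        lower = min(lo, hi), upper = max(lo, hi),
                        tol = 1e-5)
    exp(r$root)
  }
  ci <- sort(c(bound(-1), bound(+1)))
  # Poisson deviance against the saturated model
  mu <- exp(fit$par[3L]) * exp_conv_mass(edges, tau_hat, fit$par[2L], irf) +
    exp(fit$par[4L]) + 1e-12
  dev_terms <- ifelse(counts > 0, counts * log(counts / mu) - (counts - mu),
                      mu)
  deviance <- 2 * sum(dev_terms)
  structure(list(tau0 = tau_hat, ci95 = ci,
                 amplitude = exp(fit$par[3L]),
                 background = exp(fit$par[4L]),
                 t0 = fit$par[2L],
                 deviance = deviance,
                 reduced_deviance = deviance / max(length(counts) - 4, 1),
                 iterations = fit$counts[1L],
                 converged = TRUE),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime_fit: tau0 = %.1f ps, 95%% CI [%.1f, %.1f] ps>\n",
              x$tau0, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("  amplitude %.3g, background %.3g/bin, t0 %.1f ps, reduced deviance %.3g\n",
              x$amplitude, x$background, x$t0, x$reduced_deviance))
  invisible(x)
}
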