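#' Measured channel rates and efficiency of a stream
#'
#' Stream-level summary mirroring the quantities quoted for a heralded
#' fluorescence run: herald rate R_h, fluorescence-channel singles rate,
#' gated heralded-fluorescence rate R_hf (events whose gate contains at
#' least one fluorescence tag, doubles included) and the channel efficiency
#' e_hf = R_hf / R_h.
#'
#' @param stream a [tag_stream()] with a herald channel.
#' @param gate_ps fluorescence gate length (ps).
#' @return list with `R_h`, `R_fluor_singles`, `R_hf`, `e_hf`, `N_H`,
#'   `n_hf_events`, `duration_s`.
#' @export
measure_rates <- function(stream, gate_ps = 10000) {
  dur <- stream$meta$duration_s
  if (is.null(dur) || dur <= 0) stop("stream lacks a positive duration_s")
  N_H <- sum(stream$channel == 1L)
  n_f <- sum(stream$channel %in% c(2L, 3L))
  n_hf <- 0L
  if (N_H > 0 && n_f > 0) {
    d <- tryCatch(herald_count_distribution(stream, gate_ps = gate_ps),
                  error = function(e) NULL)
    if (!is.null(d)) n_hf <- d$total_events
  }
  list(R_h = N_H / dur, R_fluor_singles = n_f / dur, R_hf = n_hf / dur,
       e_hf = if (N_H > 0) n_hf / N_H else NA_real_,
       N_H = N_H, n_hf_events = n_hf, duration_s = dur)
}

#' Chi-square goodness of fit of a herald-count distribution to the
#' geometric law
#'
#' Compares the empirical counts over N >= 1 with the geometric model
#' (efficiency fitted by [fit_geometric()] unless supplied), pooling tail
#' bins so every expected count is at least `min_expected`. Degrees of
#' freedom are reduced by one when the efficiency was estimated from the
#' same data.
#'
#' @param dist a [herald_count_distribution()] result.
#' @param e_hf geometric efficiency; `NULL` fits it from `dist`.
#' @param min_expected minimum expected count per (pooled) cell.
#' @return list with `statistic`, `df`, `p_value`, `n_cells`, `e_hf`.
#' @export
chisq_geometric <- function(dist, e_hf = NULL, min_expected = 5) {
  fitted <- is.null(e_hf)
  if (fitted) e_hf <- fit_geometric(dist)$e_hf
  keep <- dist$N >= 1
  N <- dist$N[keep]
  obs <- dist$counts[keep]
  n <- sum(obs)
  p <- geometric_pn(e_hf, N)
  # everything beyond the last observed N goes into the final pooled cell
  p_tail <- (1 - e_hf)^max(N)
  exp_cnt <- n * p
  # pool from the right until all cells reach the threshold
  o_cells <- numeric(0); e_cells <- numeric(0)
  acc_o <- obs[length(obs)]; acc_e <- exp_cnt[length(exp_cnt)] + n * p_tail
  for (i in rev(seq_len(length(obs) - 1L))) {
    if (acc_e >= min_expected) {
      o_cells <- c(acc_o, o_cells); e_cells <- c(acc_e, e_cells)
      acc_o <- 0; acc_e <- 0
    }
    acc_o <- acc_o + obs[i]; acc_e <- acc_e + exp_cnt[i]
  }
  o_cells <- c(acc_o, o_cells); e_cells <- c(acc_e, e_cells)
  if (length(o_cells) < 3L)
    stop("too few cells for a chi-square test after pooling")
  stat <- sum((o_cells - e_cells)^2 / e_cells)
  df <- length(o_cells) - 1L - as.integer(fitted)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_cells = length(o_cells), e_hf = e_hf)
}

#' Exponential-tail slope of a herald-count distribution
#'
#' Single-exponential fit of the counts over N >= 1 by a Poisson
#' log-linear model (`glm` with log link), whose slope estimates `-e_hf`
#' in the small-efficiency regime where the geometric law reduces to a
#' single exponential. The Poisson likelihood avoids the low-count bias
#' that least squares on log counts would incur in the sparse tail;
#' zero-count bins within the observed range participate.
#'
#' @param dist a [herald_count_distribution()] result.
#' @return list with `slope`, `se` (standard error of the slope) and
#'   `n_bins`.
#' @export
tail_slope <- function(dist) {
  keep <- dist$N >= 1
  N <- dist$N[keep]
  cnt <- dist$counts[keep]
  if (sum(cnt > 0) < 5) stop("too few populated bins for a tail fit")
  fit <- stats::glm(cnt ~ N, family = stats::poisson())
  co <- summary(fit)$coefficients
  list(slope = co[2L, 1L], se = co[2L, 2L], n_bins = length(N))
}

.rate_label <- function(n_p) sprintf("n_p=%.4g", n_p)

#' Reproduce the cross-correlation / lifetime result set
#'
#' Simulates streams at three incident rates (mean pair numbers `n_p_set`),
#' builds the herald-fluorescence cross-correlation histogram of each at
#' 128-ps bins, estimates the IRF from the herald-residue correlation of
#' the first stream, and extracts the fluorescence lifetime of each rate by
#' IRF-reconvolution fitting.
#'
#' Desk scale: the default duration and boosted detection efficiency give
#' each stream an event count comparable to a 200-s experimental run while
#' keeping the pulse count tractable; the fluorescence lifetime estimate is
#' independent of the lumped efficiency, so the boost does not bias it.
#'
#' @param config base [experiment_config()]; its `n_p` is overridden.
#' @param n_p_set the three mean pair numbers to run.
#' @param keep_streams return the simulated streams in the report.
#' @return a run-report list with per-rate measured rates, histograms and
#'   [fit_lifetime()] results, the shared IRF estimate, and config echo.
#' @export
reproduce_fig1 <- function(config = experiment_config(duration_s = 0.5,
                                                      p_detect_fluor = 0.05,
                                                      p_detect_residue = 0.02,
                                                      seed = 1L),
                           n_p_set = c(0.0458, 0.0214, 0.0103),
                           keep_streams = FALSE) {
  t_start <- Sys.time()
  rates <- list()
  irf <- NULL
  for (i in seq_along(n_p_set)) {
    cfg <- config
    cfg$n_p <- n_p_set[i]
    cfg$seed <- config$seed + i - 1L
    stream <- simulate_stream(cfg)
    ms <- measure_rates(stream, gate_ps = cfg$gate_fluor)
    entry <- list(n_p = n_p_set[i], rates = ms)
    if (ms$N_H == 0 || ms$n_hf_events == 0) {
      entry$warning <- "empty correlation: no heralded fluorescence events"
      rates[[.rate_label(n_p_set[i])]] <- entry
      next
    }
    hist <- crosscorrelate(stream, stream, bin_ps = 128,
                           window_ps = floor(1e12 / cfg$R_r / 2))
    if (is.null(irf) && cfg$p_detect_residue > 0)
      irf <- estimate_irf(channel_times(stream, 1L),
                          channel_times(stream, 0L), bin_ps = 128)
    entry$histogram <- hist
    if (ms$n_hf_events < 1000)
      entry$warning <- sprintf("low-count stream (%d events): fit may be unstable",
                               ms$n_hf_events)
    fit_irf <- if (!is.null(irf)) irf else
      irf_gaussian(0, sqrt(2) * cfg$irf_sigma)
    entry$lifetime <- tryCatch(fit_lifetime(hist, fit_irf),
                               error = function(e) conditionMessage(e))
    if (keep_streams) entry$stream <- stream
    rates[[.rate_label(n_p_set[i])]] <- entry
  }
  list(section = "fig1", config = config, n_p_set = n_p_set, irf = irf,
       rates = rates, seed = config$seed,
       elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
}

#' Reproduce the conditional g2(0) result set
#'
#' Simulates three-detector (splitter) streams and computes the gated
#' conditional g2(0) with Poisson errors: the heralded-fluorescence value
#' at the base pair number with the fluorescence gate, and the heralded
#' *incident* values (no-sample variant: photons detected without
#' fluorescence delay) at three pair numbers with the shorter incident
#' gate. The theoretical curve 2 n_p / (1 + n_p) is attached for overlay.
#'
#' @param config base [experiment_config()]; `splitter` is forced on.
#' @param n_p_set pair numbers for the incident-photon variant.
#' @return a run-report list with `fluor` (g2 of heralded fluorescence),
#'   `incident` (per-rate g2 list) and `theory` values.
#' @export
reproduce_fig2 <- function(config = experiment_config(duration_s = 2,
                                                      p_detect_fluor = 0.05,
                                                      splitter = TRUE,
                                                      seed = 1L),
                           n_p_set = c(0.0458, 0.0214, 0.0103)) {
  t_start <- Sys.time()
  config$splitter <- TRUE
  stream <- simulate_stream(config)
  gc_f <- gated_counts(stream, gate_ps = config$gate_fluor)
  fluor <- conditional_g2(gc_f)
  incident <- list()
  for (i in seq_along(n_p_set)) {
    cfg <- config
    cfg$n_p <- n_p_set[i]
    cfg$fluorescence <- FALSE
    cfg$seed <- config$seed + 100L + i
    s <- simulate_stream(cfg)
    gc_i <- gated_counts(s, gate_ps = cfg$gate_incident)
    incident[[.rate_label(n_p_set[i])]] <-
      c(conditional_g2(gc_i), list(n_p = n_p_set[i]))
  }
  list(section = "fig2", config = config, fluor = fluor, incident = incident,
       theory = stats::setNames(heralded_g2_theory(n_p_set),
                                vapply(n_p_set, .rate_label, "")),
       seed = config$seed,
       elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
}

#' Reproduce the heralds-per-fluorescence distribution result set
#'
#' Simulates the counting experiment, builds the empirical P(N), overlays
#' the geometric model evaluated at the self-measured efficiency (with the
#' chi-square of the comparison and the exponential-tail slope), and
#' repeats the run at multiplied durations to trace how the Poisson
#' counting noise of P(N = 1) shrinks with integration time.
#'
#' @param config base [experiment_config()]; `splitter` is forced on so
#'   double events can populate the N = 0 bin.
#' @param multipliers integration-time multipliers for the noise study.
#' @param repeats independent repetitions per multiplier used to measure
#'   the s.d. of P(N = 1) empirically (in addition to the per-run Poisson
#'   estimate).
#' @return a run-report list with `distribution`, `fit`
#'   ([fit_geometric()]), `chisq`, `tail`, and `noise_study` (one row per
#'   multiplier: duration, mean and s.d. of P(N = 1)).
#' @export
reproduce_fig3 <- function(config = experiment_config(duration_s = 1,
                                                      p_detect_fluor = 0.02,
                                                      splitter = TRUE,
                                                      seed = 1L),
                           multipliers = c(1, 4),
                           repeats = 3L) {
  t_start <- Sys.time()
  config$splitter <- TRUE
  dist <- simulate_pn_experiment(config)
  fit <- fit_geometric(dist)
  chis <- chisq_geometric(dist, e_hf = fit$e_hf)
  tl <- tail_slope(dist)
  noise <- data.frame()
  for (m in multipliers) {
    cfg <- config
    cfg$duration_s <- config$duration_s * m
    cfg$seed <- config$seed + 1000L * which(multipliers == m)[1L]
    reps <- simulate_pn_experiment(cfg, repeats = repeats)
    p1 <- vapply(reps, function(d) d$prob[match(1L, d$N)], 0)
    pois <- vapply(reps, function(d) d$sd[match(1L, d$N)], 0)
    noise <- rbind(noise, data.frame(
      multiplier = m, duration_s = cfg$duration_s,
      mean_p1 = mean(p1), sd_p1 = stats::sd(p1),
      mean_poisson_sd_p1 = mean(pois)))
  }
  list(section = "fig3", config = config, distribution = dist, fit = fit,
       chisq = chis, tail = tl, noise_study = noise, seed = config$seed,
       elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
}
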